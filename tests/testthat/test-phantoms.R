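test_that("sphere phantom reproduces printed volumes and concentration", {
  g <- coarse_grid()
  ph <- coarse_sphere_phantom(g, concentration_MBq_mL = 5.80)
  vv <- voxel_volume_mL(g)
  targets <- c(0.52, 1.15, 2.72, 5.61, 11.7, 26.9)

  for (i in seq_along(targets)) {
    m <- ph$masks[[paste0("sphere", i)]]
    expect_lte(abs(sum(m) * vv - targets[i]), vv)
    expect_true(all(ph$activity[m] == 5.80))
  }
  # background cold
  hot <- Reduce(`|`, ph$masks)
  expect_true(all(ph$activity[!hot] == 0))
  # total activity consistent with sum(region volume x concentration),
  # within one boundary-voxel quantum per region
  expect_lte(
    abs(total_activity_MBq(ph) - sum(targets) * 5.80),
    length(targets) * vv * 5.80
  )
  # attenuation support contains activity support
  expect_true(all(ph$mu[ph$activity > 0] > 0))
})

test_that("sphere phantom honours zero concentration and failure modes", {
  g <- coarse_grid()
  ph0 <- coarse_sphere_phantom(g, concentration_MBq_mL = 0)
  expect_true(all(ph0$activity == 0))
  expect_true(all(ph0$mu >= 0))
  # a grid too small for the body names the problem explicitly
  expect_error(make_sphere_phantom(spect_grid(c(16, 16, 16), 4.42)),
               "grid too small")
  # a sphere pushed outside the body is named
  expect_error(
    make_sphere_phantom(coarse_grid(), body_length_mm = 150,
                        ring_radius_mm = 110),
    "sphere 2"
  )
})

test_that("largest sphere voxel count matches the 4.42 mm brute count", {
  # 26.9 mL / 0.08635 mL per voxel = 311.5 -> 311 or 312 voxels; computed
  # on a window grid large enough for sphere 6 alone
  g <- spect_grid(c(16, 16, 16), voxel_mm = 4.42)
  m <- make_voi_mask(shape_sphere(c(0, 0, 0), volume_mL = 26.9), g,
                     target_volume_mL = 26.9)
  expect_true(sum(m) %in% c(311, 312))
})

test_that("cylinder phantom volume and concentration match the analytic body", {
  g <- coarse_grid(c(32, 32, 28), 8)
  ph <- make_cylinder_phantom(g, radius_mm = 108, length_mm = 186,
                              concentration_MBq_mL = 1.0)
  vv <- voxel_volume_mL(g)
  analytic <- pi * 10.8^2 * 18.6 # 6813 mL
  vox_vol <- sum(ph$masks$cylinder) * vv
  # voxelized volume within one voxel of the target (volume-preserving rule)
  expect_lte(abs(vox_vol - analytic), vv)
  expect_true(all(ph$activity[ph$masks$cylinder] == 1.0))

  ph2 <- make_cylinder_phantom(g)
  expect_equal(unique(ph2$activity[ph2$masks$cylinder]), 0.0228)
  expect_error(make_cylinder_phantom(g, radius_mm = 0), "radius")
  expect_error(make_cylinder_phantom(g, radius_mm = 300), "exceeds")
})

test_that("anthropomorphic phantom carries the printed concentrations", {
  g <- spect_grid(c(44, 44, 32), 6.5)
  ph24 <- make_anthro_phantom(g, timepoint_h = 24)
  expect_true(all(ph24$activity[ph24$masks$tumour1] == 1.9))
  expect_true(all(ph24$activity[ph24$masks$tumour3] == 1.9))
  expect_true(all(ph24$activity[ph24$masks$spleen] == 0.51))
  expect_true(all(ph24$activity[ph24$masks$liver] == 0.14))
  expect_true(all(ph24$activity[ph24$masks$kidney_left] == 0.34))
  expect_true(all(ph24$activity[ph24$masks$kidney_right] == 0.45))

  ph168 <- make_anthro_phantom(g, timepoint_h = 168)
  expect_true(all(ph168$activity[ph168$masks$tumour2] == 0.75))
  expect_true(all(ph168$activity[ph168$masks$liver] == 0.040))
  expect_true(all(ph168$activity[ph168$masks$kidney_right] == 0.068))

  expect_error(make_anthro_phantom(g, timepoint_h = 96), "24 or 168")
})

test_that("anthro region masks are pairwise disjoint and inside the body", {
  g <- spect_grid(c(44, 44, 32), 6.5)
  ph <- make_anthro_phantom(g, timepoint_h = 24)
  nms <- names(ph$masks)
  for (i in seq_along(nms)) {
    for (j in seq_len(i - 1)) {
      expect_equal(sum(ph$masks[[i]] & ph$masks[[j]]), 0,
                   info = paste(nms[i], "vs", nms[j]))
    }
  }
  # tumour volumes within one voxel of the printed values
  vv <- voxel_volume_mL(g)
  for (k in 1:3) {
    expect_lte(abs(sum(ph$masks[[paste0("tumour", k)]]) * vv -
                     c(2.8, 8.9, 40.0)[k]), vv)
  }
  expect_true(all(ph$mu[ph$activity > 0] > 0))
})

test_that("anthro background option fills the remainder body", {
  g <- spect_grid(c(44, 44, 32), 6.5)
  ph <- make_anthro_phantom(g, timepoint_h = 24, background_MBq_mL = 0.02)
  hot <- Reduce(`|`, ph$masks)
  body <- ph$mu > 0
  expect_true(all(ph$activity[body & !hot] == 0.02))
  expect_true(all(ph$activity[!body] == 0))
})

test_that("decay factor follows the 6.647 d half-life", {
  expect_equal(decay_factor(0), 1)
  expect_equal(decay_factor(6.647), 0.5)
  expect_equal(decay_factor(13.294), 0.25)
  expect_equal(decay_factor(-6.647), 2)
  expect_error(decay_factor(Inf), "finite")
})
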