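test_that("VOI masks preserve volume within one voxel", {
  g <- spect_grid(c(24, 24, 24), voxel_mm = 4.42)
  vv <- voxel_volume_mL(g)

  # 5.61 mL / 0.08635 = 64.97 -> 64 or 65 voxels
  m <- make_voi_mask(shape_sphere(c(0, 0, 0), volume_mL = 5.61), g,
                     target_volume_mL = 5.61)
  expect_true(sum(m) %in% c(64, 65))

  # a sphere of exactly 27 voxel volumes, grid-aligned, tiles 27 voxels
  m27 <- make_voi_mask(shape_sphere(c(0, 0, 0), volume_mL = 27 * vv), g)
  expect_equal(sum(m27), 27)

  # shifted placements of the same sphere differ by at most one voxel
  m_a <- make_voi_mask(shape_sphere(c(1.3, -2.1, 0.7), volume_mL = 5.61), g)
  expect_lte(abs(sum(m_a) - sum(m)), 1)

  expect_error(
    make_voi_mask(shape_sphere(c(60, 0, 0), volume_mL = 5.61), g),
    "outside"
  )
  expect_error(
    make_voi_mask(shape_sphere(c(0, 0, 0), volume_mL = 0.01), g),
    "smaller than one voxel"
  )
})

test_that("VOI volume is preserved over randomized placements", {
  set.seed(2024)
  g <- spect_grid(c(20, 20, 20), voxel_mm = 5)
  vv <- voxel_volume_mL(g)
  for (rep in 1:25) {
    vol <- runif(1, 2, 30)
    ctr <- runif(3, -15, 15)
    m <- make_voi_mask(shape_sphere(ctr, volume_mL = vol), g,
                       target_volume_mL = vol)
    expect_lte(abs(sum(m) * vv - vol), vv)
  }
})

test_that("concentration estimation is the plain VOI mean", {
  g <- spect_grid(c(8, 8, 8), voxel_mm = 10)
  img <- array(2.5, dim = g$shape)
  mask <- array(FALSE, dim = g$shape)
  mask[c(1, 9, 100)] <- TRUE
  expect_equal(estimate_concentration(img, mask), 2.5)
  img[1] <- 0; img[9] <- 0; img[100] <- 6
  expect_equal(estimate_concentration(img, mask), 2)
  expect_error(estimate_concentration(img, mask & FALSE), "empty")
})

test_that("realization summaries reproduce the error and CV formulas", {
  rec <- summarize_realizations(c(1, 3), c_ref = 2.5)
  expect_equal(rec$c_est_mean, 2)
  expect_equal(rec$c_est_sd, sqrt(2), tolerance = 1e-12)    # n-1 denominator
  expect_equal(rec$cv, sqrt(2) / 2, tolerance = 1e-12)      # 0.70711
  expect_equal(rec$abs_mean_rel_error, 0.2)
  expect_true(rec$valid)

  perfect <- summarize_realizations(rep(4, 8), c_ref = 4)
  expect_equal(perfect$abs_mean_rel_error, 0)
  expect_equal(perfect$cv, 0)

  # all-zero estimates: CV undefined, flagged invalid
  zero <- summarize_realizations(rep(0, 5), c_ref = 1)
  expect_false(zero$valid)
  expect_true(is.na(zero$cv))
  expect_true(zero$median_zero)
  expect_error(summarize_realizations(1, 1), "two realizations")
})

test_that("summaries are invariant to a global rescaling", {
  set.seed(5)
  x <- rgamma(32, 20, 2)
  a <- summarize_realizations(x, c_ref = 9)
  b <- summarize_realizations(10 * x, c_ref = 90)
  expect_equal(a$cv, b$cv)
  expect_equal(a$abs_mean_rel_error, b$abs_mean_rel_error)
})

test_that("outliers are flagged by the 50 % median-deviation rule", {
  o <- detect_outliers(c(1, 1, 1, 1.6))
  expect_equal(sum(o$flags), 1)
  expect_true(o$setting_flagged)
  expect_false(o$median_zero)

  o2 <- detect_outliers(c(1, 1, 1, 1.4))
  expect_equal(sum(o2$flags), 0)
  expect_false(o2$setting_flagged)

  o3 <- detect_outliers(rep(0, 6))
  expect_true(o3$median_zero)
  expect_true(o3$setting_flagged)
})

test_that("plot inclusion needs two iterations, 16 updates, and validity", {
  recs <- tibble::tibble(
    n_iterations = c(1, 2, 2, 3),
    n_subsets = c(60, 4, 10, 10),
    n_updates = c(60, 8, 20, 30),
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  kept <- filter_for_plots(recs)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$n_updates, 20)
})

test_that("the relative SE of the sample SD exceeds 10 % at n = 32", {
  expect_equal(sd_rel_se(32), 1 / sqrt(62))
  expect_equal(round(100 * sd_rel_se(32), 2), 12.70)
  expect_gt(sd_rel_se(32), 0.10)
  # Monte Carlo confirmation of the closed form
  set.seed(123)
  sds <- replicate(4000, sd(rnorm(32)))
  expect_equal(sd(sds) / mean(sds), sd_rel_se(32), tolerance = 0.05)
})
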