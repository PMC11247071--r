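test_that("forward and back projection are exact adjoints (dense oracle)", {
  set.seed(42)
  g <- spect_grid(c(8, 8, 8), voxel_mm = 20)
  sys <- spect_system(pixel_mm = 20, sigma0_mm = 8, slope = 0.05,
                      sensitivity_cps_MBq = 3)
  mu <- array(runif(prod(g$shape), 0, 0.03), dim = g$shape)
  angles <- c(0, 37, 120, 245)

  A <- dense_system_matrix(mu, sys, g, angles)
  for (rep in 1:5) {
    f <- array(runif(prod(g$shape)), dim = g$shape)
    p <- array(runif(8 * 8 * length(angles)), dim = c(8, 8, length(angles)))
    lhs <- sum(forward_project(f, mu, sys, g, angles) * p)
    rhs <- sum(f * back_project(p, mu, sys, g, angles))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
    # back projector equals the explicit transpose
    expect_equal(as.vector(back_project(p, mu, sys, g, angles)),
                 as.vector(crossprod(A, as.vector(p))), tolerance = 1e-10)
  }
})

test_that("projector is linear and maps zero to zero", {
  set.seed(7)
  g <- spect_grid(c(10, 10, 8), voxel_mm = 15)
  sys <- spect_system(pixel_mm = 15, sigma0_mm = 5, slope = 0.04,
                      sensitivity_cps_MBq = 2)
  mu <- array(runif(prod(g$shape), 0, 0.02), dim = g$shape)
  angles <- projection_angles(6)
  f <- array(runif(prod(g$shape)), dim = g$shape)
  f2 <- array(runif(prod(g$shape)), dim = g$shape)

  expect_true(all(forward_project(array(0, g$shape), mu, sys, g, angles) == 0))
  lhs <- forward_project(3.5 * f + f2, mu, sys, g, angles)
  rhs <- 3.5 * forward_project(f, mu, sys, g, angles) +
    forward_project(f2, mu, sys, g, angles)
  expect_lt(max(abs(lhs - rhs)) / max(rhs), 1e-10)
})

test_that("a centred source projects identically at every angle", {
  # band-limited point source: an on-grid delta is not rotatable by linear
  # interpolation without direction-dependent smoothing
  g <- spect_grid(c(25, 25, 17), voxel_mm = 10)
  sys <- spect_system(pixel_mm = 10, sigma0_mm = 12, slope = 0.03,
                      sensitivity_cps_MBq = 1)
  f <- gaussian_blob(g, sigma_mm = 30)
  pr <- forward_project(f, array(0, g$shape), sys, g, projection_angles(8))
  dev <- max(abs(sweep(pr, c(1, 2), pr[, , 1]))) / max(pr)
  expect_lt(dev, 1e-2)
})

test_that("without attenuation and blur each angle conserves counts", {
  g <- coarse_grid()
  sys <- coarse_system(sens = 7)
  ph <- coarse_sphere_phantom(g)
  mu0 <- array(0, dim = g$shape)
  pr <- forward_project(ph$activity, mu0, sys, g, projection_angles(12))
  expected <- 7 * total_activity_MBq(ph)
  ratios <- apply(pr, 3, sum) / expected
  expect_true(all(abs(ratios - 1) <= 0.01))
})

test_that("raising attenuation never increases any projection value", {
  set.seed(11)
  g <- spect_grid(c(12, 12, 8), voxel_mm = 15)
  sys <- spect_system(pixel_mm = 15, sigma0_mm = 5, slope = 0.03,
                      sensitivity_cps_MBq = 1)
  f <- array(runif(prod(g$shape)), dim = g$shape)
  mu <- array(runif(prod(g$shape), 0, 0.02), dim = g$shape)
  p1 <- forward_project(f, mu, sys, g, c(0, 63, 170))
  for (rep in 1:5) {
    mu2 <- mu
    idx <- sample(prod(g$shape), 20)
    mu2[idx] <- mu2[idx] + 0.05
    p2 <- forward_project(f, mu2, sys, g, c(0, 63, 170))
    expect_true(all(p2 <= p1 + 1e-12))
    mu <- mu2
    p1 <- p2
  }
})

test_that("scatter model obeys its defining algebra", {
  g <- coarse_grid()
  # kernel sigma of 2 px so the plane centre is > 4 sigma from any edge
  sys <- spect_system(pixel_mm = 8, scatter_fraction = 0.2,
                      scatter_width_mm = 16)
  prim <- array(runif(32 * 20 * 3), dim = c(32, 20, 3))

  sys0 <- spect_system(pixel_mm = 8, scatter_fraction = 0)
  expect_identical(add_scatter(prim, sys0), prim)

  # uniform plane: total = primary / (1 - f) away from edges
  unif <- array(1, dim = c(32, 20, 1))
  tot <- add_scatter(unif, sys)
  centre <- tot[14:18, 9:12, 1]
  expect_equal(unname(centre), array(1 / 0.8, dim = dim(centre)),
               tolerance = 1e-3)

  # on a simulated sphere-phantom projection, scatter/total ~ f (edge loss)
  ph <- coarse_sphere_phantom(g)
  pr <- forward_project(ph$activity, ph$mu, coarse_system(blur = TRUE), g,
                        projection_angles(4))
  sc <- scatter_component(pr, sys)
  frac <- sum(sc) / sum(sc + pr)
  expect_lt(abs(frac - 0.2), 0.02)
})

test_that("grid/system mismatches are rejected", {
  g <- coarse_grid()
  sys_bad <- spect_system(pixel_mm = 5)
  ph <- coarse_sphere_phantom(g)
  expect_error(forward_project(ph$activity, ph$mu, sys_bad, g, 0),
               "pixel size")
  expect_error(
    forward_project(ph$activity[1:10, , ], ph$mu, coarse_system(), g, 0),
    "dimensions"
  )
})
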