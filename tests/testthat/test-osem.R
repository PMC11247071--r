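# Frozen scheme bookkeeping: subset lists and iteration caps per
# projection count under the even-divisor and product <= 2400 rules.
TABLE1 <- list(
  `120` = list(subs = c(2, 4, 6, 8, 10, 12, 20, 24, 30, 40, 60), iter = 20),
  `60` = list(subs = c(2, 4, 6, 10, 12, 20, 30), iter = 40),
  `40` = list(subs = c(2, 4, 8, 10, 20), iter = 60),
  `30` = list(subs = c(2, 6, 10), iter = 80),
  `24` = list(subs = c(2, 4, 6, 8, 12), iter = 100),
  `20` = list(subs = c(2, 4, 10), iter = 120)
)

test_that("scheme enumeration reproduces the constrained scheme table", {
  for (np in names(TABLE1)) {
    s <- enumerate_recon_schemes(as.integer(np))
    expect_equal(sort(unique(s$n_subsets)), TABLE1[[np]]$subs)
    expect_equal(max(s$n_iterations), TABLE1[[np]]$iter)
    expect_equal(max(s$n_updates),
                 max(TABLE1[[np]]$subs) * TABLE1[[np]]$iter)
    # every emitted scheme satisfies both constraints
    expect_true(all(s$n_subsets %% 2 == 0))
    expect_true(all(as.integer(np) %% s$n_subsets == 0))
    expect_true(all(as.integer(np) / s$n_subsets >= 2))
    expect_true(all(s$n_iterations * s$n_projections <= 2400))
  }
  total <- sum(sapply(names(TABLE1), function(np) {
    nrow(enumerate_recon_schemes(as.integer(np)))
  }))
  expect_equal(total, 1900)
})

test_that("scheme validation enforces both printed constraints", {
  expect_error(recon_scheme(60, 3, 5), "even divisor")   # odd subsets
  expect_error(recon_scheme(60, 60, 5), "even divisor")  # < 2 angles each
  expect_error(recon_scheme(60, 14, 5), "even divisor")  # non-divisor
  expect_error(recon_scheme(60, 2, 41), "budget")        # product > 2400
  s <- recon_scheme(60, 30, 40)
  expect_equal(s$n_updates, 1200)
})

test_that("interleaved subsets partition the angles", {
  s2 <- make_subsets(1:60, 2)
  expect_equal(s2[[1]], seq(1, 59, by = 2))
  expect_equal(s2[[2]], seq(2, 60, by = 2))
  s8 <- make_subsets(1:24, 8)
  expect_length(s8, 8)
  expect_true(all(lengths(s8) == 3))
  expect_equal(sort(unlist(s8)), 1:24) # each angle in exactly one subset
  expect_error(make_subsets(1:24, 5), "even divisor")
})

test_that("poisson log-likelihood matches hand computation", {
  p <- c(2, 0, 5)
  lam <- c(1.5, 0.7, 4.0)
  expect_equal(poisson_loglik(p, lam),
               2 * log(1.5) + 5 * log(4.0) - sum(lam))
  expect_equal(poisson_loglik(c(0, 0), c(2, 3)), -5)
  # p = lam maximizes over scalings of lam
  lam0 <- c(3, 1, 6)
  lls <- sapply(c(0.6, 0.8, 1, 1.25, 1.6),
                function(a) poisson_loglik(lam0, a * lam0))
  expect_equal(which.max(lls), 3)
  expect_error(poisson_loglik(c(1, 0), c(0, 1)), "zero")
})

test_that("ML-EM increases the likelihood at every iteration", {
  # uniform disk, no attenuation, delta PSF, noise-free data, one subset
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- coarse_system(voxel_mm = 16, sens = 2)
  mu0 <- array(0, dim = g$shape)
  f_true <- array(0, dim = g$shape)
  disk <- make_voi_mask(shape_cylinder(c(0, 0, 0), 70, 60), g)
  f_true[disk] <- 1
  angles <- projection_angles(8)
  lam <- forward_project(f_true, mu0, sys, g, angles)
  ps <- new_projection_set(lam, angles, 1, provenance = "noise-free")
  rec <- osem_reconstruct(ps, mu0, sys, g, recon_scheme(8, 1, 15),
                          keep_loglik = TRUE)
  dll <- diff(rec$loglik)
  expect_true(all(dll >= -1e-8 * abs(rec$loglik[-1])))
})

test_that("an exact solution is a fixed point of the OS-EM update", {
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- spect_system(pixel_mm = 16, sigma0_mm = 8, slope = 0.03,
                      sensitivity_cps_MBq = 2, scatter_fraction = 0.1)
  ph <- make_cylinder_phantom(g, radius_mm = 70, length_mm = 60,
                              concentration_MBq_mL = 0.8)
  angles <- projection_angles(8)
  prim <- forward_project(ph$activity, ph$mu, sys, g, angles)
  sct <- scatter_component(prim, sys)
  ps <- new_projection_set(prim + sct, angles, 1)
  rec <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(8, 2, 1),
                          scatter_estimate = sct, initial = ph$activity)
  f1 <- rec$snapshots[[1]]
  rel <- abs(f1 - ph$activity) / max(ph$activity)
  expect_lt(max(rel), 1e-8)
})

test_that("ML-EM converges to count consistency on noise-free data", {
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- spect_system(pixel_mm = 16, sigma0_mm = 6, slope = 0.02,
                      sensitivity_cps_MBq = 2, scatter_fraction = 0.1)
  ph <- make_cylinder_phantom(g, radius_mm = 70, length_mm = 60,
                              concentration_MBq_mL = 0.8)
  angles <- projection_angles(8)
  prim <- forward_project(ph$activity, ph$mu, sys, g, angles)
  sct <- scatter_component(prim, sys)
  ps <- new_projection_set(prim + sct, angles, 1)
  rec <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(8, 1, 200),
                          scatter_estimate = sct)
  f <- rec$snapshots[[200]]
  model <- forward_project(f, ph$mu, sys, g, angles) + sct
  expect_lt(abs(sum(model) - sum(ps$counts)) / sum(ps$counts), 1e-3)
})

test_that("snapshots are nonnegative and deterministic", {
  set.seed(8)
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- coarse_system(voxel_mm = 16, blur = TRUE)
  ph <- make_cylinder_phantom(g, radius_mm = 70, length_mm = 60,
                              concentration_MBq_mL = 0.3)
  ps <- simulate_acquisition(ph, sys, 8, 60, seed = 4)
  rec1 <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(8, 4, 3))
  rec2 <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(8, 4, 3))
  expect_length(rec1$snapshots, 3)
  for (snap in rec1$snapshots) expect_true(all(snap >= 0))
  expect_identical(rec1$snapshots, rec2$snapshots)
})

test_that("all-zero projections return a zero image with a warning", {
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- coarse_system(voxel_mm = 16)
  mu <- array(0.01, dim = g$shape)
  ps <- new_projection_set(array(0, dim = c(16, 8, 8)),
                           projection_angles(8), 10)
  expect_warning(
    rec <- osem_reconstruct(ps, mu, sys, g, recon_scheme(8, 2, 2)),
    "all-zero"
  )
  expect_true(all(rec$snapshots[[2]] == 0))
})

test_that("noise-free recovery error shrinks with updates", {
  # large-sphere VOI mean approaches truth as updates accumulate
  g <- coarse_grid()
  sys <- spect_system(pixel_mm = 8, sensitivity_cps_MBq = 3)
  ph <- coarse_sphere_phantom(g)
  angles <- projection_angles(12)
  prim <- forward_project(ph$activity, ph$mu, sys, g, angles)
  sct <- scatter_component(prim, sys)
  ps <- new_projection_set(prim + sct, angles, 1)
  rec <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(12, 2, 24),
                          scatter_estimate = sct)
  est <- sapply(rec$snapshots, function(f) mean(f[ph$masks$sphere6]))
  err <- abs(est / 5.80 - 1)
  expect_lt(err[24], err[8])   # 48 vs 16 updates
  expect_lt(err[8], err[1])    # 16 vs 2 updates
})

test_that("tidy and glance summarize a reconstruction", {
  g <- spect_grid(c(16, 16, 8), voxel_mm = 16)
  sys <- coarse_system(voxel_mm = 16)
  ph <- make_cylinder_phantom(g, radius_mm = 70, length_mm = 60,
                              concentration_MBq_mL = 0.3)
  ps <- simulate_acquisition(ph, sys, 8, 60, seed = 4)
  rec <- osem_reconstruct(ps, ph$mu, sys, g, recon_scheme(8, 2, 3))
  td <- tidy(rec)
  expect_equal(td$iteration, 1:3)
  expect_equal(td$n_updates, c(2, 4, 6))
  gl <- glance(rec)
  expect_equal(gl$n_updates, 6)
  expect_gte(gl$min_voxel, 0)
})
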