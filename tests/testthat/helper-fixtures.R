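# Small-scale fixtures shared across tests. Physical phantom geometry is
# kept (mm), only the grid is coarsened so desk-scale runs stay fast.

coarse_grid <- function(shape = c(32, 32, 20), voxel_mm = 8) {
  spect_grid(shape, voxel_mm)
}

# System matched to a coarse grid; delta PSF and zero scatter unless asked.
coarse_system <- function(voxel_mm = 8, blur = FALSE, scatter = 0,
                          sens = 5) {
  spect_system(
    pixel_mm = voxel_mm,
    sigma0_mm = if (blur) 6 else 0,
    slope = if (blur) 0.04 else 0,
    sensitivity_cps_MBq = sens,
    scatter_fraction = scatter
  )
}

# Sphere phantom on a coarse grid (shorter body so it fits axially).
coarse_sphere_phantom <- function(grid = coarse_grid(), ...) {
  make_sphere_phantom(grid, body_length_mm = 150, ...)
}

# Isotropic Gaussian blob (band-limited stand-in for a point source).
gaussian_blob <- function(grid, sigma_mm, centre_mm = c(0, 0, 0)) {
  ax <- lapply(grid$shape, function(n) (seq_len(n) - (n + 1) / 2) * grid$voxel_mm)
  f <- array(0, dim = grid$shape)
  gx <- exp(-0.5 * (ax[[1]] - centre_mm[1])^2 / sigma_mm^2)
  gy <- exp(-0.5 * (ax[[2]] - centre_mm[2])^2 / sigma_mm^2)
  gz <- exp(-0.5 * (ax[[3]] - centre_mm[3])^2 / sigma_mm^2)
  for (k in seq_len(grid$shape[3])) f[, , k] <- outer(gx, gy) * gz[k]
  f
}

# Dense system matrix of the forward projector, built column by column.
# Only feasible on tiny grids; the independent oracle for adjointness.
dense_system_matrix <- function(mu, system, grid, angles) {
  nvox <- prod(grid$shape)
  npix <- grid$shape[1] * grid$shape[3] * length(angles)
  A <- matrix(0, nrow = npix, ncol = nvox)
  for (k in seq_len(nvox)) {
    e <- array(0, dim = grid$shape)
    e[k] <- 1
    A[, k] <- as.vector(forward_project(e, mu, system, grid, angles))
  }
  A
}

# Hand-rolled time-binned object for bootstrap unit tests.
fake_time_binned <- function(bins, angles_deg = NULL) {
  d <- dim(bins)
  if (is.null(angles_deg)) angles_deg <- (seq_len(d[4]) - 1) * 360 / d[4]
  structure(
    list(bins = bins, angles_deg = angles_deg, bin_s = 1, seed = NULL),
    class = "time_binned_projections"
  )
}

# O(n^2) pairwise-domination oracle for Pareto flags.
pareto_oracle <- function(error, cv) {
  n <- length(error)
  vapply(seq_len(n), function(i) {
    !any(error <= error[i] & cv <= cv[i] & (error < error[i] | cv < cv[i]))
  }, logical(1))
}
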