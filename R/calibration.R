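#' Calibration factor from a uniform-phantom reconstruction
#'
#' The factor converting reconstructed count-rate concentration to
#' activity concentration: the reference concentration divided by the
#' mean reconstructed signal in a central VOI. Applying the factor to the
#' reconstruction it was derived from returns the reference concentration
#' in that VOI exactly.
#'
#' @param image Reconstructed volume (count-rate units).
#' @param mask Logical VOI mask.
#' @param ref_concentration Known activity concentration (MBq/mL).
#' @return Scalar calibration factor.
#' @export
compute_calibration_factor <- function(image, mask, ref_concentration) {
  m <- estimate_concentration(image, mask)
  if (m <= 0) stop("mean VOI signal is not positive; factor undefined",
                   call. = FALSE)
  ref_concentration / m
}

#' Central cylindrical calibration VOI
#'
#' A cylinder coaxial with the calibration phantom, radius 60 % of the
#' phantom radius and length chosen to reach the target VOI volume (the
#' protocol specifies only the VOI volumes, 375 mL for the measured and
#' 1953 mL for the simulated calibration).
#'
#' @param grid A [spect_grid()].
#' @param voi_volume_mL Target VOI volume (mL).
#' @param phantom_radius_mm Calibration-phantom radius (default 108 mm).
#' @return Logical mask.
#' @export
calibration_voi_mask <- function(grid, voi_volume_mL,
                                 phantom_radius_mm = 108) {
  r <- 0.6 * phantom_radius_mm
  len <- voi_volume_mL * 1000 / (pi * r^2)
  make_voi_mask(shape_cylinder(c(0, 0, 0), r, len), grid,
                target_volume_mL = voi_volume_mL)
}

#' Per-scheme calibration factors from a noise-free cylinder
#'
#' Simulates the uniform calibration cylinder without Poisson noise
#' (emulating a long calibration acquisition), reconstructs it with every
#' requested scheme under the matched compensation model, and derives one
#' calibration factor per (projections, subsets, iterations) setting.
#'
#' @param schemes Tibble as from [enumerate_recon_schemes()] (columns
#'   `n_projections`, `n_subsets`, `n_iterations`).
#' @param grid A [spect_grid()].
#' @param system A [spect_system()].
#' @param voi_volume_mL Calibration VOI volume (default 375 mL).
#' @param cylinder_radius_mm,cylinder_length_mm,concentration_MBq_mL
#'   Calibration-cylinder geometry and concentration.
#' @return The scheme tibble with an appended `factor` column.
#' @export
calibrate_all <- function(schemes, grid, system, voi_volume_mL = 375,
                          cylinder_radius_mm = 108,
                          cylinder_length_mm = 186,
                          concentration_MBq_mL = 0.0228) {
  stopifnot(all(c("n_projections", "n_subsets", "n_iterations") %in%
                  names(schemes)))
  phantom <- make_cylinder_phantom(
    grid, radius_mm = cylinder_radius_mm, length_mm = cylinder_length_mm,
    concentration_MBq_mL = concentration_MBq_mL
  )
  voi <- calibration_voi_mask(grid, voi_volume_mL,
                              phantom_radius_mm = cylinder_radius_mm)

  groups <- dplyr::distinct(schemes, .data$n_projections, .data$n_subsets)
  rates_by_n <- list()
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    np <- groups$n_projections[g]
    ns <- groups$n_subsets[g]
    key <- as.character(np)
    if (is.null(rates_by_n[[key]])) {
      rates_by_n[[key]] <- expected_rates(phantom, system,
                                          projection_angles(np))
    }
    rates <- rates_by_n[[key]]
    iters <- sort(unique(
      schemes$n_iterations[schemes$n_projections == np &
                             schemes$n_subsets == ns]
    ))
    max_iter <- max(iters)
    ps <- new_projection_set(rates$total, projection_angles(np), 1,
                             provenance = "noise-free calibration")
    scheme <- recon_scheme(np, ns, max_iter,
                           max_product = max(2400, np * max_iter))
    rec <- osem_reconstruct(ps, phantom$mu, system, grid, scheme,
                            scatter_estimate = rates$total - rates$primary)
    out[[g]] <- tibble::tibble(
      n_projections = np, n_subsets = ns, n_iterations = iters,
      factor = vapply(iters, function(it) {
        compute_calibration_factor(rec$snapshots[[it]], voi,
                                   concentration_MBq_mL)
      }, numeric(1))
    )
  }
  dplyr::left_join(
    schemes, dplyr::bind_rows(out),
    by = c("n_projections", "n_subsets", "n_iterations")
  )
}
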