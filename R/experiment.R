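#' Study configuration for the sphere-phantom bootstrap arm
#'
#' Defaults describe a desk-scale version of the emulated study: the full
#' protocol (120 base projections at 180 s, all six projection counts,
#' three acquisition times, 32 realizations, the full scheme table) is
#' obtained with `full = TRUE` but takes hours; the defaults keep the
#' stated phantom, count-rate anchor and protocol structure while
#' reducing the sweep so a run completes in minutes.
#'
#' @param grid_shape,voxel_mm Reconstruction/phantom grid.
#' @param projection_counts Projection counts to study (subset of the
#'   divisors of `n_base_projections`).
#' @param times_min Total virtual acquisition times (minutes).
#' @param n_realizations Noise realizations per setting.
#' @param n_base_projections,time_per_projection_s Base acquisition that
#'   is bootstrapped.
#' @param subsets Optional subset counts to restrict the scheme table to
#'   (default: all admissible).
#' @param max_iterations Optional cap on iterations per scheme (default:
#'   the `max_product` rule alone).
#' @param max_product Iterations-times-projections budget (default 2400).
#' @param target_rate_cps Count-rate anchor for the sensitivity.
#' @param concentration_MBq_mL Sphere concentration.
#' @param body_length_mm Axial length of the phantom body (shrink for
#'   short test grids).
#' @param calibration_voi_mL Calibration VOI volume.
#' @param calibration_cylinder_mm Radius and length of the calibration
#'   cylinder (defaults to the 10.8 cm / 18.6 cm phantom; shrink with the
#'   grid for desk-scale runs).
#' @param seed Root seed for all randomness.
#' @param full If `TRUE`, expand to the full printed protocol.
#' @return A named configuration list.
#' @export
sphere_arm_config <- function(grid_shape = c(64, 64, 48), voxel_mm = 4.42,
                              projection_counts = c(20, 60),
                              times_min = 10,
                              n_realizations = 8,
                              n_base_projections = 120,
                              time_per_projection_s = 180,
                              subsets = c(2, 4, 10),
                              max_iterations = 12,
                              max_product = 2400,
                              target_rate_cps = 700,
                              concentration_MBq_mL = 5.80,
                              body_length_mm = 170,
                              calibration_voi_mL = 375,
                              calibration_cylinder_mm = c(108, 186),
                              seed = 1,
                              full = FALSE) {
  cfg <- list(
    grid_shape = grid_shape, voxel_mm = voxel_mm,
    projection_counts = projection_counts, times_min = times_min,
    n_realizations = n_realizations,
    n_base_projections = n_base_projections,
    time_per_projection_s = time_per_projection_s,
    subsets = subsets, max_iterations = max_iterations,
    max_product = max_product, target_rate_cps = target_rate_cps,
    concentration_MBq_mL = concentration_MBq_mL,
    body_length_mm = body_length_mm,
    calibration_voi_mL = calibration_voi_mL,
    calibration_cylinder_mm = calibration_cylinder_mm, seed = seed
  )
  if (full) {
    cfg$projection_counts <- c(20, 24, 30, 40, 60, 120)
    cfg$times_min <- c(10, 20, 40)
    cfg$n_realizations <- 32
    cfg$subsets <- NULL
    cfg$max_iterations <- NULL
    warning("full protocol requested: expect a multi-hour run")
  }
  cfg
}

#' @rdname sphere_arm_config
#' @param timepoints_h Imaging time points for the anthropomorphic arm.
#' @export
anthro_arm_config <- function(grid_shape = c(64, 64, 48), voxel_mm = 4.42,
                              projection_counts = c(20, 60),
                              times_min = 10,
                              n_realizations = 8,
                              timepoints_h = c(24, 168),
                              subsets = c(2, 4, 10),
                              max_iterations = 12,
                              max_product = 2400,
                              target_rate_cps = 700,
                              calibration_voi_mL = 1953,
                              calibration_cylinder_mm = c(108, 186),
                              seed = 1,
                              full = FALSE) {
  cfg <- list(
    grid_shape = grid_shape, voxel_mm = voxel_mm,
    projection_counts = projection_counts, times_min = times_min,
    n_realizations = n_realizations, timepoints_h = timepoints_h,
    subsets = subsets, max_iterations = max_iterations,
    max_product = max_product, target_rate_cps = target_rate_cps,
    calibration_voi_mL = calibration_voi_mL,
    calibration_cylinder_mm = calibration_cylinder_mm, seed = seed
  )
  if (full) {
    cfg$projection_counts <- c(20, 24, 30, 40, 60, 120)
    cfg$times_min <- c(10, 20, 40)
    cfg$n_realizations <- 32
    cfg$subsets <- NULL
    cfg$max_iterations <- NULL
    warning("full protocol requested: expect a multi-hour run")
  }
  cfg
}

validate_arm_config <- function(cfg, anthro = FALSE) {
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  if (length(cfg$grid_shape) != 3 || any(cfg$grid_shape < 8)) {
    add("grid_shape: need three dimensions of at least 8 voxels")
  }
  if (!is.numeric(cfg$voxel_mm) || cfg$voxel_mm <= 0) {
    add("voxel_mm: must be positive")
  }
  allowed_n <- c(20, 24, 30, 40, 60, 120)
  if (!all(cfg$projection_counts %in% allowed_n)) {
    add(sprintf("projection_counts: must be a subset of {%s}",
                paste(allowed_n, collapse = ", ")))
  }
  if (!all(cfg$times_min %in% c(10, 20, 40))) {
    add("times_min: must be a subset of {10, 20, 40}")
  }
  if (!is.numeric(cfg$n_realizations) || cfg$n_realizations < 2) {
    add("n_realizations: need at least 2")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    add("seed: need a single integer")
  }
  if (anthro && !all(cfg$timepoints_h %in% c(24, 168))) {
    add("timepoints_h: must be a subset of {24, 168}")
  }
  if (length(problems) > 0) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

# Scheme table for a configuration: the admissibility rules, restricted to
# the configured subsets/iterations.
config_schemes <- function(cfg) {
  schemes <- dplyr::bind_rows(lapply(
    cfg$projection_counts, enumerate_recon_schemes,
    max_product = cfg$max_product
  ))
  if (!is.null(cfg$subsets)) {
    schemes <- dplyr::filter(schemes, .data$n_subsets %in% cfg$subsets)
  }
  if (!is.null(cfg$max_iterations)) {
    schemes <- dplyr::filter(schemes, .data$n_iterations <= cfg$max_iterations)
  }
  if (nrow(schemes) == 0) {
    stop("configuration admits no reconstruction schemes", call. = FALSE)
  }
  schemes
}

# Reconstruct one projection set once per (n_subsets) group at the group's
# maximum iteration count and extract per-iteration VOI count-rate means.
# Returns a tibble (n_subsets, n_iterations, voi, rate_mean).
quantify_recon <- function(ps, mu, system, grid, schemes_n, masks,
                           scatter_estimate) {
  groups <- split(schemes_n$n_iterations, schemes_n$n_subsets)
  np <- unique(schemes_n$n_projections)
  out <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    ns <- as.integer(names(groups)[gi])
    iters <- sort(unique(groups[[gi]]))
    scheme <- recon_scheme(np, ns, max(iters),
                           max_product = max(2400, np * max(iters)))
    rec <- osem_reconstruct(ps, mu, system, grid, scheme,
                            scatter_estimate = scatter_estimate)
    rows <- tidyr::expand_grid(n_iterations = iters, voi = names(masks))
    rows$rate_mean <- purrr::map2_dbl(
      rows$n_iterations, rows$voi,
      function(it, v) mean(rec$snapshots[[it]][masks[[v]]])
    )
    rows$n_subsets <- ns
    out[[gi]] <- rows
  }
  dplyr::bind_rows(out)
}

# Shared tail of both arms: per-realization rate means -> calibrated
# estimates -> summaries over realizations.
summarize_arm <- function(raw, factors, refs, ref_keys = "voi",
                          group_extra = character()) {
  raw |>
    dplyr::left_join(factors,
                     by = c("n_projections", "n_subsets", "n_iterations")) |>
    dplyr::left_join(refs, by = ref_keys) |>
    dplyr::mutate(estimate = .data$rate_mean * .data$factor) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(
      "phantom", "voi", group_extra, "n_projections", "total_time_min",
      "n_subsets", "n_iterations"
    )))) |>
    dplyr::group_modify(
      ~ summarize_realizations(.x$estimate, c_ref = .x$c_ref[1])
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(n_updates = .data$n_subsets * .data$n_iterations)
}

finalize_arm <- function(records, group_vars, out_dir, csv_name) {
  kept <- filter_for_plots(records)
  flagged <- pareto_front(kept, group_vars = group_vars)
  records <- dplyr::left_join(
    records, dplyr::select(flagged, dplyr::all_of(c(
      group_vars, "n_projections", "n_subsets", "n_iterations", "on_front"
    ))),
    by = c(group_vars, "n_projections", "n_subsets", "n_iterations")
  ) |>
    dplyr::mutate(on_front = !is.na(.data$on_front) & .data$on_front)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(records, file.path(out_dir, csv_name))
    fig <- plot_fronts(as_pareto_records(records |>
                                           dplyr::filter(.data$valid)),
                       facets = group_vars)
    # figure writing is best-effort: headless devices may be unavailable
    try(ggplot2::ggsave(
      file.path(out_dir, sub("\\.csv$", ".png", csv_name)),
      fig, width = 10, height = 7, dpi = 150
    ), silent = TRUE)
  }
  as_pareto_records(records)
}

#' Run the sphere-phantom bootstrap arm end-to-end
#'
#' Simulates the time-binned base acquisition of the six-sphere phantom,
#' bootstraps every configured (projection count, acquisition time)
#' setting, reconstructs every admissible scheme, calibrates against the
#' noise-free uniform cylinder, quantifies all six spheres, and flags
#' Pareto-optimal settings per sphere and acquisition time.
#'
#' @param config A [sphere_arm_config()].
#' @param out_dir Optional output directory for the records CSV and a
#'   front figure.
#' @return A `pareto_records` tibble with one row per
#'   (sphere, projection count, time, subsets, iterations).
#' @export
run_sphere_arm <- function(config = sphere_arm_config(), out_dir = NULL) {
  validate_arm_config(config)
  grid <- spect_grid(config$grid_shape, config$voxel_mm)
  phantom <- make_sphere_phantom(
    grid, concentration_MBq_mL = config$concentration_MBq_mL,
    body_length_mm = config$body_length_mm %||% 170
  )
  system <- calibrate_sensitivity(
    phantom, spect_system(pixel_mm = config$voxel_mm),
    target_rate_cps = config$target_rate_cps,
    n_projections = config$n_base_projections
  )
  schemes <- config_schemes(config)
  cyl <- config$calibration_cylinder_mm %||% c(108, 186)
  factors <- calibrate_all(schemes, grid, system,
                           voi_volume_mL = config$calibration_voi_mL,
                           cylinder_radius_mm = cyl[1],
                           cylinder_length_mm = cyl[2])

  tb <- simulate_time_binned(
    phantom, system, n_projections = config$n_base_projections,
    time_per_projection_s = config$time_per_projection_s,
    seed = child_seed(config$seed, 101)
  )

  base_rates <- expected_rates(phantom, system,
                               projection_angles(config$n_base_projections))
  raw <- list()
  for (np in config$projection_counts) {
    keep <- subsample_angles(config$n_base_projections, np)
    scatter_est <- (base_rates$total - base_rates$primary)[, , keep,
                                                           drop = FALSE]
    schemes_n <- dplyr::filter(schemes, .data$n_projections == np)
    for (tt in config$times_min) {
      realizations <- bootstrap_projections(
        tb, np, tt, n_realizations = config$n_realizations,
        seed = child_seed(config$seed, 202)
      )
      for (r in seq_along(realizations)) {
        q <- quantify_recon(realizations[[r]], phantom$mu, system, grid,
                            schemes_n, phantom$masks, scatter_est)
        q$n_projections <- np
        q$total_time_min <- tt
        q$realization <- r
        raw[[length(raw) + 1]] <- q
      }
    }
  }
  raw <- dplyr::bind_rows(raw)
  raw$phantom <- "spheres"

  refs <- tibble::tibble(
    voi = phantom$regions$label,
    c_ref = phantom$regions$concentration_MBq_mL
  )
  records <- summarize_arm(raw, factors, refs)
  finalize_arm(records, c("voi", "total_time_min"), out_dir,
               "sphere_arm_records.csv")
}

#' Run the anthropomorphic simulation arm end-to-end
#'
#' Noise-free forward projections of the anthropomorphic phantom at each
#' time point are scaled to the configured acquisition times; Poisson
#' noise realizations are reconstructed with every admissible scheme,
#' calibrated against the noise-free cylinder (1953 mL VOI), and the
#' three tumours quantified; Pareto flags are per tumour, acquisition
#' time and time point.
#'
#' @param config An [anthro_arm_config()].
#' @param out_dir Optional output directory.
#' @return A `pareto_records` tibble.
#' @export
run_anthro_arm <- function(config = anthro_arm_config(), out_dir = NULL) {
  validate_arm_config(config, anthro = TRUE)
  grid <- spect_grid(config$grid_shape, config$voxel_mm)
  # one camera for the whole study: anchor the sensitivity on the sphere
  # phantom's aggregate count rate
  anchor <- make_sphere_phantom(grid)
  system <- calibrate_sensitivity(
    anchor, spect_system(pixel_mm = config$voxel_mm),
    target_rate_cps = config$target_rate_cps
  )
  schemes <- config_schemes(config)
  cyl <- config$calibration_cylinder_mm %||% c(108, 186)
  factors <- calibrate_all(schemes, grid, system,
                           voi_volume_mL = config$calibration_voi_mL,
                           cylinder_radius_mm = cyl[1],
                           cylinder_length_mm = cyl[2])

  raw <- list()
  for (tp in config$timepoints_h) {
    phantom <- make_anthro_phantom(grid, timepoint_h = tp)
    tumour_masks <- phantom$masks[grep("^tumour", names(phantom$masks))]
    for (np in config$projection_counts) {
      rates <- expected_rates(phantom, system, projection_angles(np))
      scatter_est <- rates$total - rates$primary
      schemes_n <- dplyr::filter(schemes, .data$n_projections == np)
      for (tt in config$times_min) {
        t_per <- tt * 60 / np
        lambda <- rates$total * t_per
        for (r in seq_len(config$n_realizations)) {
          counts <- with_seed(
            child_seed(config$seed, 303, tp, np, tt, r),
            array(rpois(length(lambda), lambda), dim = dim(lambda))
          )
          ps <- new_projection_set(counts, projection_angles(np), t_per,
                                   provenance = "simulated")
          q <- quantify_recon(ps, phantom$mu, system, grid, schemes_n,
                              tumour_masks, scatter_est)
          q$n_projections <- np
          q$total_time_min <- tt
          q$timepoint_h <- tp
          q$realization <- r
          raw[[length(raw) + 1]] <- q
        }
      }
    }
  }
  raw <- dplyr::bind_rows(raw)
  raw$phantom <- "anthro"

  refs_by_tp <- dplyr::bind_rows(lapply(config$timepoints_h, function(tp) {
    conc <- ANTHRO_CONCENTRATIONS[[as.character(tp)]]
    tibble::tibble(
      voi = paste0("tumour", 1:3), timepoint_h = tp,
      c_ref = conc[["tumour"]]
    )
  }))

  records <- summarize_arm(raw, factors, refs_by_tp,
                           ref_keys = c("voi", "timepoint_h"),
                           group_extra = "timepoint_h")
  finalize_arm(records, c("voi", "timepoint_h", "total_time_min"), out_dir,
               "anthro_arm_records.csv")
}
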