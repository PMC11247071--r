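#' Construct a projection set
#'
#' Container for ordered 2-D count images with their acquisition angles,
#' time per projection (virtual time) and provenance. Normally produced
#' by [simulate_acquisition()] or [bootstrap_projections()]; exported so
#' externally generated or file-loaded projections can enter the
#' pipeline.
#'
#' @param counts Array `(n_u, n_v, n_angles)` of nonnegative counts (or
#'   expected counts for noise-free sets).
#' @param angles_deg Acquisition angles (degrees), one per projection.
#' @param time_per_projection_s Virtual time per projection (s).
#' @param provenance Free-text origin tag.
#' @param seed Seed the counts were drawn with, if any.
#' @return A `projection_set`.
#' @export
new_projection_set <- function(counts, angles_deg, time_per_projection_s,
                               provenance = "simulated", seed = NULL) {
  structure(
    list(
      counts = counts, angles_deg = angles_deg,
      time_per_projection_s = time_per_projection_s,
      provenance = provenance, seed = seed
    ),
    class = "projection_set"
  )
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<projection_set> %d projections (%dx%d), %.4g s each, %s, %.3g counts total\n",
    d[3], d[1], d[2], x$time_per_projection_s, x$provenance, sum(x$counts)
  ))
  invisible(x)
}

# Noiseless total (primary + scatter) count-rate projections for a phantom.
expected_rates <- function(phantom, system, angles_deg) {
  primary <- forward_project(phantom$activity, phantom$mu, system,
                             grid = phantom$grid, angles_deg = angles_deg)
  list(primary = primary, total = add_scatter(primary, system))
}

#' Simulate a Poisson SPECT acquisition
#'
#' Computes noiseless total count-rate projections (attenuation,
#' distance-dependent blur, additive scatter) at equally spaced angles
#' over 360 degrees, scales by the time per projection, and draws
#' independent Poisson counts. Reproducible for a given seed.
#'
#' @param phantom A `spect_phantom`.
#' @param system A [spect_system()].
#' @param n_projections Number of projections over 360 degrees.
#' @param total_time_s Total (virtual) acquisition time in seconds,
#'   divided equally over the projections.
#' @param seed Integer seed; `NULL` uses the session RNG.
#' @param noise If `FALSE`, return the expected counts without Poisson
#'   noise.
#' @return A `projection_set` whose `counts` has shape
#'   `(n_u, n_v, n_projections)`.
#' @export
simulate_acquisition <- function(phantom, system, n_projections = 120,
                                 total_time_s, seed = NULL, noise = TRUE) {
  stopifnot(inherits(phantom, "spect_phantom"))
  if (n_projections < 1) stop("need at least one projection", call. = FALSE)
  if (total_time_s <= 0) stop("`total_time_s` must be positive", call. = FALSE)
  angles <- projection_angles(n_projections)
  t_per <- total_time_s / n_projections
  lambda <- expected_rates(phantom, system, angles)$total * t_per
  counts <- if (noise) {
    with_seed(seed, array(rpois(length(lambda), lambda), dim = dim(lambda)))
  } else {
    lambda
  }
  new_projection_set(counts, angles, t_per,
                     provenance = if (noise) "simulated" else "noise-free",
                     seed = seed)
}

#' Simulate a time-binned acquisition (list-mode surrogate)
#'
#' Draws independent Poisson counts for every 1-s time bin of every
#' detector pixel and angle — the surrogate for list-mode data that the
#' bootstrap resamples. Summing over bins reproduces a full-time
#' acquisition exactly.
#'
#' @inheritParams simulate_acquisition
#' @param time_per_projection_s Time per projection in whole seconds
#'   (default 180, the emulated protocol).
#' @param bin_s Bin duration; fixed at 1 s.
#' @return A `time_binned_projections` object with integer `bins` of
#'   shape `(n_u, n_v, n_bins, n_projections)`.
#' @export
simulate_time_binned <- function(phantom, system, n_projections = 120,
                                 time_per_projection_s = 180, seed = NULL,
                                 bin_s = 1) {
  stopifnot(inherits(phantom, "spect_phantom"), bin_s == 1)
  if (time_per_projection_s <= 0 ||
      abs(time_per_projection_s - round(time_per_projection_s)) > 1e-9) {
    stop("`time_per_projection_s` must be a positive whole number of seconds",
         call. = FALSE)
  }
  nt <- as.integer(round(time_per_projection_s))
  angles <- projection_angles(n_projections)
  rate <- expected_rates(phantom, system, angles)$total # counts/s per pixel
  d <- dim(rate)
  bins <- array(0L, dim = c(d[1], d[2], nt, n_projections))
  with_seed(seed, {
    for (a in seq_len(n_projections)) {
      lam <- rep(as.vector(rate[, , a]), times = nt)
      bins[, , , a] <- array(rpois(length(lam), lam), dim = c(d[1], d[2], nt))
    }
  })
  structure(
    list(bins = bins, angles_deg = angles, bin_s = 1, seed = seed),
    class = "time_binned_projections"
  )
}

#' @export
print.time_binned_projections <- function(x, ...) {
  d <- dim(x$bins)
  cat(sprintf(
    "<time_binned_projections> %d angles x %d bins of 1 s, %dx%d pixels\n",
    d[4], d[3], d[1], d[2]
  ))
  invisible(x)
}

#' Sum time bins into a full-time projection set
#' @param tb A `time_binned_projections`.
#' @return A `projection_set` with time per projection equal to the number
#'   of bins.
#' @export
sum_time_bins <- function(tb) {
  stopifnot(inherits(tb, "time_binned_projections"))
  d <- dim(tb$bins)
  counts <- apply(tb$bins, c(1, 2, 4), sum)
  new_projection_set(counts, tb$angles_deg, d[3],
                     provenance = "time-binned sum", seed = tb$seed)
}
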