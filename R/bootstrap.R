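#' Constant-stride angular subsampling
#'
#' Selects `n_projections` of the available angles with constant angular
#' spacing, starting at the first angle. The requested count must divide
#' the available count.
#'
#' @param n_available Number of acquired projections (default 120).
#' @param n_projections Number to retain (a divisor of `n_available`).
#' @return 1-based indices into the available angles.
#' @examples
#' subsample_angles(120, 30) # every 4th angle
#' @export
subsample_angles <- function(n_available = 120, n_projections) {
  if (n_projections < 1 || n_available %% n_projections != 0) {
    stop(sprintf("%d projections cannot be drawn from %d with constant spacing",
                 n_projections, n_available), call. = FALSE)
  }
  seq(1, n_available, by = n_available / n_projections)
}

#' Bootstrap reduced-time, reduced-angle acquisitions
#'
#' Emulates shorter acquisitions from time-binned projection data:
#' retains `n_projections` angles at constant spacing, and for each
#' realization, retained angle and detector pixel sums
#' `k = total_time_min * 60 / n_projections` time bins drawn uniformly
#' with replacement from that pixel's bin sequence. Pixels and angles are
#' resampled independently. Acquisition times are virtual (single-head)
#' times.
#'
#' @param tb A `time_binned_projections`.
#' @param n_projections Number of retained projections (divisor of the
#'   acquired count).
#' @param total_time_min Total virtual acquisition time in minutes; the
#'   implied per-pixel draw count `k` must be a positive integer.
#' @param n_realizations Number of bootstrap realizations (default 32).
#' @param seed Root seed; each realization uses a derived child seed.
#' @return A list of `projection_set` objects, one per realization, with
#'   `time_per_projection_s = total_time_min * 60 / n_projections`.
#' @export
bootstrap_projections <- function(tb, n_projections, total_time_min,
                                  n_realizations = 32, seed = NULL) {
  stopifnot(inherits(tb, "time_binned_projections"))
  if (n_realizations < 1) stop("need at least one realization", call. = FALSE)
  d <- dim(tb$bins)
  n_avail <- d[4]
  nt <- d[3]
  keep <- subsample_angles(n_avail, n_projections)
  t_per <- total_time_min * 60 / n_projections
  k <- total_time_min * 60 / n_projections
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop("total time does not correspond to a whole number of 1-s bins per projection",
         call. = FALSE)
  }
  k <- as.integer(round(k))
  if (k > 2 * nt) {
    warning(sprintf(
      "drawing %d bins per pixel from only %d acquired bins (heavy reuse)",
      k, nt
    ))
  }

  npix <- d[1] * d[2]
  lapply(seq_len(n_realizations), function(r) {
    rseed <- child_seed(seed, n_projections, total_time_min, r)
    counts <- array(0, dim = c(d[1], d[2], length(keep)))
    with_seed(rseed, {
      for (ai in seq_along(keep)) {
        a <- keep[ai]
        bins_a <- matrix(tb$bins[, , , a], nrow = npix, ncol = nt)
        tidx <- sample.int(nt, npix * k, replace = TRUE)
        vals <- bins_a[cbind(rep(seq_len(npix), each = k), tidx)]
        counts[, , ai] <- matrix(colSums(matrix(vals, nrow = k)),
                                 nrow = d[1], ncol = d[2])
      }
    })
    new_projection_set(counts, tb$angles_deg[keep], t_per,
                       provenance = "bootstrapped", seed = rseed)
  })
}
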