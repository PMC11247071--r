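#' Validate a reconstruction scheme
#'
#' A scheme `(n_projections, n_subsets, n_iterations)` is valid when the
#' number of subsets is an even integer divisor of the number of
#' projections with at least two angles per subset, and the product of
#' iterations and projections does not exceed `max_product` (a proxy for
#' a fixed reconstruction-time budget).
#'
#' @param n_projections Number of projections.
#' @param n_subsets Number of OS-EM subsets.
#' @param n_iterations Number of full iterations.
#' @param max_product Cap on `n_iterations * n_projections` (default 2400).
#' @return A `recon_scheme` list with the derived `n_updates`.
#' @export
recon_scheme <- function(n_projections, n_subsets, n_iterations,
                         max_product = 2400) {
  # n_subsets = 1 is the ML-EM special case, admitted for analysis/tests
  # but never emitted by the scheme enumeration
  if (n_subsets != 1 &&
      (n_subsets < 2 || n_subsets %% 2 != 0 ||
       n_projections %% n_subsets != 0 || n_projections / n_subsets < 2)) {
    stop(sprintf(
      "%d subsets is not an even divisor of %d projections with >= 2 angles each",
      n_subsets, n_projections), call. = FALSE)
  }
  if (n_iterations < 1) stop("need at least one iteration", call. = FALSE)
  if (n_iterations * n_projections > max_product) {
    stop(sprintf("iterations x projections = %d exceeds the budget of %d",
                 n_iterations * n_projections, max_product), call. = FALSE)
  }
  structure(
    list(n_projections = n_projections, n_subsets = n_subsets,
         n_iterations = n_iterations,
         n_updates = n_subsets * n_iterations),
    class = "recon_scheme"
  )
}

#' Enumerate all admissible reconstruction schemes
#'
#' All `(n_subsets, n_iterations)` combinations for a given number of
#' projections: subsets are the even divisors of the projection count
#' with at least two angles per subset; iterations run from 1 to
#' `floor(max_product / n_projections)`.
#'
#' @inheritParams recon_scheme
#' @return A tibble with columns `n_projections`, `n_subsets`,
#'   `n_iterations`, `n_updates`.
#' @examples
#' s <- enumerate_recon_schemes(60)
#' unique(s$n_subsets) # 2 4 6 10 12 20 30
#' max(s$n_iterations) # 40
#' @export
enumerate_recon_schemes <- function(n_projections, max_product = 2400) {
  stopifnot(n_projections >= 4)
  divs <- which(n_projections %% seq_len(n_projections) == 0)
  subs <- divs[divs %% 2 == 0 & n_projections / divs >= 2]
  max_iter <- floor(max_product / n_projections)
  tidyr::expand_grid(
    n_projections = as.integer(n_projections),
    n_subsets = as.integer(subs),
    n_iterations = seq_len(max_iter)
  ) |>
    dplyr::mutate(n_updates = .data$n_subsets * .data$n_iterations)
}

#' Partition angles into interleaved ordered subsets
#'
#' Subset `i` contains angle indices `i, i + S, i + 2S, ...` (interleaved
#' over the circle); subsets are processed in natural order.
#'
#' @param angle_idx Vector of angle indices (or any angle identifiers).
#' @param n_subsets Number of subsets (even divisor rule as in
#'   [recon_scheme()]).
#' @return List of `n_subsets` equally sized index groups.
#' @export
make_subsets <- function(angle_idx, n_subsets) {
  n <- length(angle_idx)
  if (n_subsets == 1) return(list(angle_idx))
  if (n_subsets < 2 || n_subsets %% 2 != 0 || n %% n_subsets != 0 ||
      n / n_subsets < 2) {
    stop(sprintf(
      "%d subsets is not an even divisor of %d angles with >= 2 angles each",
      n_subsets, n), call. = FALSE)
  }
  lapply(seq_len(n_subsets), function(i) {
    angle_idx[seq(i, n, by = n_subsets)]
  })
}

#' Poisson log-likelihood of projections under expected counts
#'
#' `sum(p * log(lambda) - lambda)` with constant terms dropped; the
#' objective ML-EM maximizes.
#'
#' @param p Observed counts (nonnegative).
#' @param expected Expected counts `lambda`; must be positive wherever
#'   `p > 0`.
#' @return Scalar log-likelihood.
#' @export
poisson_loglik <- function(p, expected) {
  if (any(expected <= 0 & p > 0)) {
    stop("expected counts are zero where observed counts are positive",
         call. = FALSE)
  }
  pos <- p > 0
  sum(p[pos] * log(expected[pos])) - sum(expected)
}

#' OS-EM reconstruction with matched compensation
#'
#' Ordered-subsets expectation maximization with the package's projector
#' (attenuation and distance-dependent resolution in the system matrix,
#' scatter as an additive term in the forward model):
#' `f <- f / (A_S' 1) * A_S' ( p_S / (A_S f + s_S) )`
#' for each subset S in natural interleaved order. Projections are
#' normalized to count rate (counts/s) before reconstruction, so the
#' reconstructed voxel values are count-rate concentrations that a
#' cylinder-derived calibration factor converts to MBq/mL. A snapshot is
#' kept after each full iteration.
#'
#' @param proj A `projection_set`.
#' @param mu Attenuation volume (cm^-1) on `grid`.
#' @param system A [spect_system()].
#' @param grid The reconstruction [spect_grid()].
#' @param scheme A [recon_scheme()] (its `n_projections` must match the
#'   projection set).
#' @param scatter_estimate Additive scatter estimate in counts/s, shape
#'   `(n_u, n_v, n_angles)`; defaults to zero (no scatter compensation).
#' @param keep_loglik If `TRUE`, record the Poisson log-likelihood of the
#'   full data after every iteration (costs one extra forward projection
#'   per iteration).
#' @param initial Optional initial estimate volume; defaults to a uniform
#'   positive value inside the attenuation support (zero outside).
#' @return An `osem_result` with per-iteration `snapshots` (count-rate
#'   volumes), the `scheme`, and optionally `loglik`.
#' @export
osem_reconstruct <- function(proj, mu, system, grid, scheme,
                             scatter_estimate = NULL, keep_loglik = FALSE,
                             initial = NULL) {
  stopifnot(inherits(proj, "projection_set"), inherits(scheme, "recon_scheme"))
  n_ang <- dim(proj$counts)[3]
  if (scheme$n_projections != n_ang) {
    stop("scheme projection count does not match the projection set",
         call. = FALSE)
  }
  if (any(proj$counts < 0)) stop("projections must be nonnegative", call. = FALSE)
  p_rate <- proj$counts / proj$time_per_projection_s
  if (is.null(scatter_estimate)) {
    scatter_estimate <- array(0, dim = dim(p_rate))
  }
  if (!identical(dim(scatter_estimate), dim(p_rate))) {
    stop("scatter estimate shape does not match the projections", call. = FALSE)
  }

  snapshots <- vector("list", scheme$n_iterations)
  loglik <- if (keep_loglik) numeric(scheme$n_iterations) else NULL

  if (sum(p_rate) == 0) {
    warning("all-zero projections: returning a zero image")
    zero <- new_volume(grid)
    for (i in seq_len(scheme$n_iterations)) snapshots[[i]] <- zero
    return(structure(
      list(snapshots = snapshots, scheme = scheme, loglik = loglik,
           grid = grid),
      class = "osem_result"
    ))
  }

  subsets <- make_subsets(seq_len(n_ang), scheme$n_subsets)
  angles <- proj$angles_deg
  support <- if (any(mu > 0)) mu > 0 else array(TRUE, dim = grid$shape)

  # per-subset sensitivity images A_S' 1
  sens_img <- lapply(subsets, function(s) {
    ones <- array(1, dim = c(dim(p_rate)[1], dim(p_rate)[2], length(s)))
    back_project(ones, mu, system, grid, angles[s])
  })

  if (is.null(initial)) {
    # uniform start at the data-implied mean concentration; scaling with
    # the data keeps OS-EM exactly scale-equivariant at any iteration
    f <- new_volume(grid)
    f[support] <- sum(p_rate) / (n_ang * system$sensitivity_cps_MBq *
                                   voxel_volume_mL(grid) * sum(support))
  } else {
    f <- ensure_dim(initial, grid)
    if (any(f < 0)) stop("initial estimate must be nonnegative", call. = FALSE)
  }

  for (it in seq_len(scheme$n_iterations)) {
    for (si in seq_along(subsets)) {
      s <- subsets[[si]]
      lam <- forward_project(f, mu, system, grid, angles[s]) +
        scatter_estimate[, , s, drop = FALSE]
      eps <- 1e-12 * mean(lam[lam > 0])
      lam[lam < eps] <- eps
      ratio <- p_rate[, , s, drop = FALSE] / lam
      bp <- back_project(ratio, mu, system, grid, angles[s])
      denom <- sens_img[[si]]
      upd <- array(1, dim = grid$shape)
      ok <- denom > 0
      upd[ok] <- bp[ok] / denom[ok]
      f <- f * upd
    }
    snapshots[[it]] <- f
    if (keep_loglik) {
      lam_all <- (forward_project(f, mu, system, grid, angles) +
                    scatter_estimate) * proj$time_per_projection_s
      eps <- 1e-12 * mean(lam_all[lam_all > 0])
      lam_all[lam_all < eps] <- eps
      loglik[it] <- poisson_loglik(proj$counts, lam_all)
    }
  }

  structure(
    list(snapshots = snapshots, scheme = scheme, loglik = loglik, grid = grid),
    class = "osem_result"
  )
}

#' @export
print.osem_result <- function(x, ...) {
  cat(sprintf(
    "<osem_result> %d projections, %d subsets, %d iterations (%d updates)\n",
    x$scheme$n_projections, x$scheme$n_subsets, x$scheme$n_iterations,
    x$scheme$n_updates
  ))
  invisible(x)
}

#' Tidy per-iteration summary of an OS-EM reconstruction
#'
#' @param x An `osem_result`.
#' @param ... Unused.
#' @return A tibble with one row per iteration: the update count, total
#'   reconstructed signal, and (if recorded) the Poisson log-likelihood.
#' @method tidy osem_result
#' @export
tidy.osem_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$snapshots),
    n_updates = seq_along(x$snapshots) * x$scheme$n_subsets,
    total_signal = vapply(x$snapshots, sum, numeric(1)),
    loglik = if (is.null(x$loglik)) NA_real_ else x$loglik
  )
}

#' One-row summary of an OS-EM reconstruction
#'
#' @param x An `osem_result`.
#' @param ... Unused.
#' @return A one-row tibble with the scheme and final-image summaries.
#' @method glance osem_result
#' @export
glance.osem_result <- function(x, ...) {
  final <- x$snapshots[[length(x$snapshots)]]
  tibble::tibble(
    n_projections = x$scheme$n_projections,
    n_subsets = x$scheme$n_subsets,
    n_iterations = x$scheme$n_iterations,
    n_updates = x$scheme$n_updates,
    total_signal = sum(final),
    min_voxel = min(final),
    final_loglik = if (is.null(x$loglik)) NA_real_ else tail(x$loglik, 1)
  )
}
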