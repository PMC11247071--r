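#' Pareto-front identification for bias versus precision
#'
#' Flags records that are Pareto optimal under joint minimization of the
#' absolute mean relative error (bias) and the CV (precision): a record
#' is on the front when no other record is at least as good in both
#' coordinates and strictly better in one. Records with identical
#' coordinates share front membership. Invalid records (undefined CV)
#' must be filtered out first (see [filter_for_plots()]).
#'
#' @param records Tibble of quantification records.
#' @param error_col,cv_col Column names of the two minimized coordinates.
#' @param group_vars Optional character vector of grouping columns; fronts
#'   are computed within each group (e.g. per VOI and acquisition time).
#' @return `records` with a logical `on_front` column, classed
#'   `pareto_records`.
#' @export
pareto_front <- function(records, error_col = "abs_mean_rel_error",
                         cv_col = "cv", group_vars = NULL) {
  if (nrow(records) == 0) {
    records$on_front <- logical(0)
    return(as_pareto_records(records))
  }
  if (anyNA(records[[error_col]]) || anyNA(records[[cv_col]])) {
    stop("coordinates contain missing values; filter invalid records first",
         call. = FALSE)
  }
  flag_group <- function(df) {
    df$on_front <- pareto_flags(df[[error_col]], df[[cv_col]])
    df
  }
  out <- if (is.null(group_vars)) {
    flag_group(records)
  } else {
    records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
      dplyr::group_modify(~ flag_group(.x)) |>
      dplyr::ungroup()
  }
  as_pareto_records(out)
}

as_pareto_records <- function(df) {
  class(df) <- unique(c("pareto_records", class(df)))
  df
}

#' Pareto-optimality flags for a point set
#'
#' Sweep algorithm: points are processed in increasing order of the first
#' coordinate; within each tie group only the minimum of the second
#' coordinate survives, and only if it strictly improves on the best
#' value seen at smaller first coordinates.
#'
#' @param error,cv Finite numeric vectors of equal length (both
#'   minimized).
#' @return Logical vector of front membership.
#' @export
pareto_flags <- function(error, cv) {
  stopifnot(length(error) == length(cv), all(is.finite(error)),
            all(is.finite(cv)))
  n <- length(error)
  if (n == 0) return(logical(0))
  flags <- logical(n)
  best_cv <- Inf
  for (e in sort(unique(error))) {
    grp <- which(error == e)
    cmin <- min(cv[grp])
    if (cmin < best_cv) {
      flags[grp[cv[grp] == cmin]] <- TRUE
      best_cv <- cmin
    }
  }
  flags
}

#' Summarize the composition of a Pareto front
#'
#' Reports, per group, the range of update numbers on the front, the
#' subset counts at the two extremes (the lowest-CV and the lowest-error
#' front points), and the projection counts represented — the quantities
#' used to characterize which reconstruction regimes populate the front
#' ends.
#'
#' @param records A `pareto_records` tibble (with `on_front`).
#' @param group_vars Optional grouping columns.
#' @return A tibble with one row per group.
#' @export
front_composition <- function(records, group_vars = NULL) {
  summarise_front <- function(df) {
    f <- df[df$on_front, , drop = FALSE]
    if (nrow(f) == 0) {
      return(tibble::tibble(
        n_front = 0L, min_updates = NA_integer_, max_updates = NA_integer_,
        subsets_at_low_cv = NA_integer_, subsets_at_low_error = NA_integer_,
        projection_counts = NA_character_
      ))
    }
    tibble::tibble(
      n_front = nrow(f),
      min_updates = min(f$n_updates),
      max_updates = max(f$n_updates),
      subsets_at_low_cv = f$n_subsets[which.min(f$cv)],
      subsets_at_low_error = f$n_subsets[which.min(f$abs_mean_rel_error)],
      projection_counts = paste(sort(unique(f$n_projections)), collapse = ",")
    )
  }
  if (is.null(group_vars)) {
    summarise_front(records)
  } else {
    records |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_vars))) |>
      dplyr::group_modify(~ summarise_front(.x)) |>
      dplyr::ungroup()
  }
}

#' Scatter plot of CV versus absolute mean relative error
#'
#' Front members are coloured by subset count with marker shape by
#' projection count; dominated points are grey. The error axis can be
#' capped (points above the cap are hidden from the panel but never
#' removed from the data).
#'
#' @param records A `pareto_records` tibble.
#' @param cap_error_percent Optional upper limit (in %) for the error
#'   axis.
#' @param facets Optional character vector of faceting columns (e.g.
#'   `c("voi", "total_time_min")`).
#' @return A ggplot object.
#' @export
plot_fronts <- function(records, cap_error_percent = NULL, facets = NULL) {
  df <- dplyr::mutate(
    records,
    error_pct = 100 * .data$abs_mean_rel_error,
    cv_pct = 100 * .data$cv
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cv_pct, y = .data$error_pct)) +
    ggplot2::geom_point(
      data = dplyr::filter(df, !.data$on_front),
      colour = "grey60", shape = 8, size = 1
    ) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$on_front),
      ggplot2::aes(colour = factor(.data$n_subsets),
                   shape = factor(.data$n_projections)),
      size = 2
    ) +
    ggplot2::labs(
      x = "CV (%)", y = "absolute mean relative error (%)",
      colour = "subsets", shape = "projections"
    ) +
    ggplot2::theme_bw()
  if (!is.null(facets)) {
    p <- p + ggplot2::facet_wrap(facets, scales = "free")
  }
  if (!is.null(cap_error_percent)) {
    p <- p + ggplot2::coord_cartesian(ylim = c(0, cap_error_percent))
  }
  p
}

#' @rdname plot_fronts
#' @param object A `pareto_records` tibble.
#' @param ... Passed to [plot_fronts()].
#' @importFrom ggplot2 autoplot
#' @method autoplot pareto_records
#' @export
autoplot.pareto_records <- function(object, ...) {
  plot_fronts(object, ...)
}
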