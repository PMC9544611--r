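#' Tidy the zero-intercept sweep fit
#'
#' @param x A `sweep_fit` object from [sweep_fit()].
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value` for the slope.
#' @exportS3Method generics::tidy
tidy.sweep_fit <- function(x, ...) {
  s <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = "variance",
    estimate = s[1L, "Estimate"],
    std.error = s[1L, "Std. Error"],
    statistic = s[1L, "t value"],
    p.value = s[1L, "Pr(>|t|)"]
  )
}

#' @rdname tidy.sweep_fit
#' @return `glance()`: a one-row tibble with `slope`, `predicted_slope`,
#'   `r.squared` (zero-intercept definition), and `n`.
#' @exportS3Method generics::glance
glance.sweep_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, predicted_slope = x$predicted_slope,
                 r.squared = x$r_squared, n = x$n)
}

#' Summaries of bootstrap ratio distributions
#'
#' @param x A `q_bootstrap` tibble.
#' @param ... Unused.
#' @return `tidy()`: one row per group with the mean, median, standard
#'   deviation and central 95% range of the bootstrap ratios. `glance()`:
#'   one row with the replicate count `b`, the seed, and the total number of
#'   degenerate (monomorphic) replicates.
#' @exportS3Method generics::tidy
tidy.q_bootstrap <- function(x, ...) {
  x |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      median = stats::median(.data$ratio),
      sd = stats::sd(.data$ratio),
      q2.5 = stats::quantile(.data$ratio, 0.025),
      q97.5 = stats::quantile(.data$ratio, 0.975),
      .groups = "drop"
    )
}

#' @rdname tidy.q_bootstrap
#' @exportS3Method generics::glance
glance.q_bootstrap <- function(x, ...) {
  tibble::tibble(
    b = attr(x, "b"),
    n_groups = length(unique(x$group)),
    seed = attr(x, "seed"),
    n_degenerate = sum(attr(x, "n_degenerate"))
  )
}
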