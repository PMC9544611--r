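#' Stacked-bar plot of one or more Q matrices
#'
#' The standard structure-style visualization: one vertical bar per
#' individual, segment heights equal to the membership coefficients, total
#' height 1. Several matrices are shown as one panel per group. Segment
#' stacking follows the input column order; no cluster alignment across
#' matrices is attempted (aligning clusters between independent runs is a
#' separate problem addressed by other tools).
#'
#' @param q A Q matrix, or a (optionally named) list of Q matrices plotted
#'   as facets.
#' @param sort_individuals If `TRUE`, individuals are ordered within each
#'   panel by their membership in the highest-mean cluster (decreasing),
#'   which gives the familiar sorted bar plot; the default keeps input
#'   order.
#' @param palette Optional vector of fill colours, one per cluster.
#' @return A `ggplot` object; its data contain one row per individual and
#'   cluster (`group`, `individual`, `cluster`, `membership`).
#' @examples
#' q <- simulate_q(30, alpha = 1, lam = c(2/3, 1/3), seed = 4)
#' plot_q(q, sort_individuals = TRUE)
#' @export
plot_q <- function(q, sort_individuals = FALSE, palette = NULL) {
  qs <- if (is.data.frame(q) || is.matrix(q)) list(q) else q
  labels <- names(qs)
  long <- purrr::map_dfr(seq_along(qs), function(pos) {
    qq <- q_matrix(q_values(qs[[pos]]), col_labels = colnames(qs[[pos]]))
    grp <- if (!is.null(labels) && nzchar(labels[[pos]])) labels[[pos]]
      else attr(qs[[pos]], "group")
    if (is.null(grp)) grp <- paste0("group", pos)
    dplyr::mutate(
      tidyr::pivot_longer(
        dplyr::mutate(qq, individual = dplyr::row_number()),
        cols = -"individual", names_to = "cluster",
        values_to = "membership"
      ),
      group = grp, .before = 1L
    )
  })
  long$cluster <- factor(long$cluster, levels = unique(long$cluster))
  if (sort_individuals) {
    long <- long |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ {
        top <- .x |>
          dplyr::group_by(.data$cluster) |>
          dplyr::summarise(mm = mean(.data$membership)) |>
          dplyr::slice_max(.data$mm, n = 1, with_ties = FALSE)
        ord <- .x |>
          dplyr::filter(.data$cluster == top$cluster) |>
          dplyr::arrange(dplyr::desc(.data$membership))
        dplyr::mutate(.x, individual = match(.data$individual,
                                             ord$individual))
      }) |>
      dplyr::ungroup()
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(
    x = .data$individual, y = .data$membership, fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = "Individual", y = "Membership", fill = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
  if (length(qs) > 1L) {
    p <- p + ggplot2::facet_wrap(~group, scales = "free_x")
  }
  if (!is.null(palette)) p <- p + ggplot2::scale_fill_manual(values = palette)
  p
}

#' Violin plot of bootstrap ratio distributions
#'
#' One violin (with the median marked) per group of a [bootstrap_ratios()] /
#' [bootstrap_groups()] result, mirroring the way bootstrap distributions of
#' FST/FSTmax are usually displayed next to the bar plots.
#'
#' @param object A `q_bootstrap` tibble.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @exportS3Method ggplot2::autoplot
autoplot.q_bootstrap <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$group, y = .data$ratio, fill = .data$group)) +
    ggplot2::geom_violin(scale = "width", show.legend = FALSE) +
    ggplot2::stat_summary(fun = stats::median, geom = "point",
                          show.legend = FALSE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = expression(F[ST] / F[ST]^max)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a variance sweep with its zero-intercept fit
#'
#' @param object A `variance_sweep` tibble.
#' @param ... Unused.
#' @return A `ggplot` object showing every replicate ratio against the
#'   parametric Dirichlet variance plus the fitted line through the origin.
#' @exportS3Method ggplot2::autoplot
autoplot.variance_sweep <- function(object, ...) {
  slope <- sweep_fit(object)$slope
  ggplot2::ggplot(object, ggplot2::aes(x = .data$variance, y = .data$ratio)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = slope, colour = "red") +
    ggplot2::labs(x = "Parametric Dirichlet variance",
                  y = expression(F[ST] / F[ST]^max)) +
    ggplot2::theme_minimal()
}
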