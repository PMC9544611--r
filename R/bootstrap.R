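#' Bootstrap distribution of FST / FSTmax
#'
#' Resamples the rows (individuals) of a Q matrix with replacement `b` times,
#' keeping the number of rows fixed, and computes FST/FSTmax for every
#' replicate matrix. A replicate that happens to be monomorphic (every
#' resampled individual fully assigned to one cluster, so FST is undefined)
#' is assigned ratio 0 and counted in the `n_degenerate` attribute, with a
#' warning; dropping such replicates would silently shrink `b`.
#'
#' @inheritParams normalize_rows
#' @param b Number of bootstrap replicates (1000 in typical use).
#' @param seed Integer seed making the resampling reproducible; if `NULL`, a
#'   seed is drawn once and recorded, so the result always carries the seed
#'   that regenerates it.
#' @param group Group label for the output; defaults to the label attached
#'   to `q`, if any.
#' @return A tibble of class `q_bootstrap` with columns `group`, `replicate`
#'   and `ratio`, and attributes `b`, `seed` and `n_degenerate`.
#' @examples
#' q <- simulate_q(i_count = 20, alpha = 2, lam = c(2/3, 1/3), seed = 1)
#' bootstrap_ratios(q, b = 50, seed = 7)
#' @seealso [bootstrap_groups()] to bootstrap several matrices under one
#'   master seed, [compare_groups()] for the rank tests.
#' @export
bootstrap_ratios <- function(q, b = 1000, seed = NULL, group = NULL) {
  mat <- q_values(q)
  if (b < 1) stop("b must be at least 1", call. = FALSE)
  if (het_total(mat) <= .ht_eps) {
    stop("monomorphic Q matrix: every bootstrap replicate would be undefined",
         call. = FALSE)
  }
  if (is.null(group)) group <- attr(q, "group")
  if (is.null(group)) group <- "group1"
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  i <- nrow(mat)
  ratios <- withr::with_seed(seed, {
    vapply(seq_len(b), function(r) {
      .q_ratio(mat[sample.int(i, i, replace = TRUE), , drop = FALSE],
               degenerate = -1)
    }, numeric(1))
  })
  n_degenerate <- sum(ratios < 0)
  if (n_degenerate > 0L) {
    warning(sprintf(
      "%d of %d bootstrap replicate(s) were monomorphic; their ratio is 0",
      n_degenerate, b), call. = FALSE)
    ratios[ratios < 0] <- 0
  }
  out <- tibble::tibble(group = as.character(group),
                        replicate = seq_len(b), ratio = ratios)
  attr(out, "b") <- b
  attr(out, "seed") <- seed
  attr(out, "n_degenerate") <- n_degenerate
  class(out) <- c("q_bootstrap", class(out))
  out
}

#' Bootstrap several groups under one master seed
#'
#' Applies [bootstrap_ratios()] to each Q matrix in a named list. Each
#' group's resampling stream is derived deterministically from the master
#' seed and the group's position, so appending further groups never perturbs
#' the draws of earlier ones.
#'
#' @param qs Named list of Q matrices (names are the group labels; unnamed
#'   entries fall back to the matrix's own `group` attribute, then to
#'   `group<i>`).
#' @inheritParams bootstrap_ratios
#' @return A `q_bootstrap` tibble with one block of `b` rows per group;
#'   attribute `seed` holds the master seed, `group_seeds` the per-group
#'   streams, and `n_degenerate` the per-group degenerate counts.
#' @export
bootstrap_groups <- function(qs, b = 1000, seed = NULL) {
  stopifnot(is.list(qs), length(qs) >= 1L)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  labels <- names(qs)
  if (is.null(labels)) labels <- rep("", length(qs))
  seeds <- .group_seeds(seed, length(qs))
  parts <- purrr::map(seq_along(qs), function(pos) {
    grp <- labels[[pos]]
    if (is.na(grp) || !nzchar(grp)) grp <- attr(qs[[pos]], "group")
    if (is.null(grp) || !nzchar(grp)) grp <- paste0("group", pos)
    bootstrap_ratios(qs[[pos]], b = b, seed = seeds[[pos]], group = grp)
  })
  out <- dplyr::bind_rows(parts)
  attr(out, "b") <- b
  attr(out, "seed") <- seed
  attr(out, "group_seeds") <- seeds
  attr(out, "n_degenerate") <- vapply(parts, attr, integer(1), "n_degenerate")
  class(out) <- c("q_bootstrap", setdiff(class(out), "q_bootstrap"))
  out
}

# deterministic per-group streams below 2^31, independent of group count
.group_seeds <- function(seed, n) {
  (as.double(seed) + 7919 * seq_len(n)) %% .Machine$integer.max
}

#' Compare bootstrap distributions of FST / FSTmax between groups
#'
#' For two groups, a two-sided Wilcoxon (Mann-Whitney) rank-sum test of
#' their bootstrap ratio distributions; for three or more, a Kruskal-Wallis
#' test across all groups plus all pairwise rank-sum tests. P-values use the
#' normal approximation with tie correction (bootstrap samples are far too
#' large for exact enumeration). If every value in both groups of a pair is
#' identical the rank-sum p-value is 1 by convention (no location difference
#' is detectable). Pairwise p-values are reported raw by default; Bonferroni
#' or Benjamini-Hochberg adjustment is available via `adjust`.
#'
#' @param x A `q_bootstrap` tibble containing at least two groups (e.g. from
#'   [bootstrap_groups()]), or a list of `q_bootstrap` objects which are
#'   combined first.
#' @param adjust Multiplicity adjustment for the pairwise p-values: one of
#'   `"none"`, `"bonferroni"`, `"bh"`.
#' @return A tibble with columns `test`, `group1`, `group2`, `statistic`,
#'   `p_value`, `p_adjusted` (`NA` unless `adjust != "none"`; the omnibus
#'   Kruskal-Wallis row is never adjusted).
#' @export
compare_groups <- function(x, adjust = c("none", "bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  if (is.list(x) && !is.data.frame(x)) x <- dplyr::bind_rows(x)
  stopifnot(all(c("group", "ratio") %in% names(x)))
  groups <- unique(x$group)
  if (length(groups) < 2L) {
    stop("compare_groups() needs at least 2 groups", call. = FALSE)
  }
  by_group <- split(x$ratio, factor(x$group, levels = groups))
  if (any(lengths(by_group) < 2L)) {
    stop("every group needs at least 2 bootstrap values", call. = FALSE)
  }

  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    a <- by_group[[p[[1L]]]]
    bvals <- by_group[[p[[2L]]]]
    if (length(unique(c(a, bvals))) == 1L) {
      stat <- length(a) * length(bvals) / 2
      pv <- 1
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, bvals, exact = FALSE, correct = TRUE)
      )
      stat <- unname(wt$statistic)
      pv <- wt$p.value
    }
    tibble::tibble(test = "rank-sum", group1 = p[[1L]], group2 = p[[2L]],
                   statistic = stat, p_value = pv)
  })
  pairwise$p_adjusted <- if (adjust == "none") NA_real_ else {
    stats::p.adjust(pairwise$p_value,
                    method = if (adjust == "bh") "BH" else "bonferroni")
  }

  if (length(groups) == 2L) return(pairwise)
  kw <- stats::kruskal.test(by_group)
  omnibus <- tibble::tibble(
    test = "kruskal-wallis", group1 = NA_character_, group2 = NA_character_,
    statistic = unname(kw$statistic), p_value = kw$p.value,
    p_adjusted = NA_real_
  )
  dplyr::bind_rows(omnibus, pairwise)
}
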