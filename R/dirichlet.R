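#' Simulate a Q matrix under the Dirichlet model
#'
#' Draws `i_count` independent membership vectors from a Dirichlet
#' distribution with parameter vector `alpha * lam`, one per row. `lam`
#' (summing to 1) sets the parametric mean membership of each cluster and
#' `alpha` controls variability: `Var(q_k) = lam_k * (1 - lam_k) / (alpha +
#' 1)`, so large `alpha` gives near-identical rows and small `alpha` gives
#' rows concentrated near the vertices of the simplex.
#'
#' Sampling normalizes independent gamma variates with shapes `alpha *
#' lam_k`. At extreme small `alpha` a whole row of gamma draws can underflow
#' to zero in double precision; such rows are redrawn and counted in the
#' `n_resampled` attribute. (A row with *some* zero entries is the correct
#' vertex limit and is kept.)
#'
#' @param i_count Number of individuals (rows) to draw.
#' @param alpha Dirichlet concentration, `> 0`.
#' @param lam Numeric vector of parametric mean membership coefficients,
#'   entries `>= 0` summing to 1; its length sets the number of clusters. A
#'   `lam_k = 1` entry makes the distribution degenerate at `lam` (allowed,
#'   but flagged with a warning).
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param group Optional group label attached to the result.
#' @return A `q_matrix` tibble with `i_count` rows.
#' @examples
#' q <- simulate_q(50, alpha = 101/99, lam = c(2/3, 1/3), seed = 1)
#' q_stat(q)
#' @export
simulate_q <- function(i_count, alpha, lam, seed = NULL, group = NULL) {
  stopifnot(i_count >= 1, alpha > 0, all(lam >= 0))
  if (abs(sum(lam) - 1) > 1e-8) stop("lam must sum to 1", call. = FALSE)
  if (any(lam == 1)) {
    warning("a lam entry equals 1: the Dirichlet is degenerate and every ",
            "row equals lam", call. = FALSE)
    mat <- matrix(rep(lam, each = i_count), nrow = i_count)
    return(q_matrix(mat, group = group))
  }
  draw <- function() .rdirichlet_rows(i_count, alpha * lam)
  res <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- q_matrix(res$mat, group = group, tol = 1e-6)
  attr(out, "n_resampled") <- res$n_resampled
  out
}

# gamma-normalization Dirichlet sampler; all-zero rows (underflow at tiny
# shape parameters) are redrawn
.rdirichlet_rows <- function(n, shape) {
  k <- length(shape)
  g <- matrix(stats::rgamma(n * k, shape = shape), nrow = n, ncol = k,
              byrow = TRUE)
  s <- rowSums(g)
  n_resampled <- 0L
  while (any(s == 0)) {
    idx <- which(s == 0)
    n_resampled <- n_resampled + length(idx)
    g[idx, ] <- matrix(stats::rgamma(length(idx) * k, shape = shape),
                       nrow = length(idx), ncol = k, byrow = TRUE)
    s <- rowSums(g)
  }
  list(mat = g / s, n_resampled = n_resampled)
}

#' Concentration parameter that yields a target membership variance
#'
#' Inverts `Var(q_k) = lam_k * (1 - lam_k) / (alpha + 1)`:
#' `alpha = lam_k * (1 - lam_k) / target_var - 1`. Vectorized over
#' `target_var`.
#'
#' @param target_var Desired variance of the membership coefficient of a
#'   cluster with mean `lam_k`; must satisfy
#'   `0 < target_var < lam_k * (1 - lam_k)`.
#' @param lam_k Parametric mean membership of the cluster, in `(0, 1)`.
#' @return The concentration `alpha`, same length as `target_var`.
#' @examples
#' alpha_from_variance(0.001, 2/3) # 21901/99
#' alpha_from_variance(0.22, 2/3)  # 1/99
#' @export
alpha_from_variance <- function(target_var, lam_k) {
  stopifnot(length(lam_k) == 1L, lam_k > 0, lam_k < 1)
  vmax <- lam_k * (1 - lam_k)
  if (any(target_var <= 0) || any(target_var >= vmax)) {
    stop(sprintf("target_var must lie in (0, %g) for lam_k = %g", vmax, lam_k),
         call. = FALSE)
  }
  vmax / target_var - 1
}

#' Variance grid of the slope experiment
#'
#' The 45 parametric variances `{0.001} U {0.005, 0.010, ..., 0.220}` used
#' in the variance-sweep validation with `lam = (2/3, 1/3)`; they span
#' nearly the whole admissible range `(0, 2/9)`.
#'
#' @return A numeric vector of length 45.
#' @export
sweep_variances <- function() {
  c(0.001, seq(0.005, 0.220, by = 0.005))
}

#' Sweep FST / FSTmax over a grid of Dirichlet variances
#'
#' For each variance in the grid, converts it to a concentration `alpha` via
#' [alpha_from_variance()], simulates `reps` replicate Q matrices of
#' `i_count` rows from `Dir(alpha * lam)`, and records FST/FSTmax for each.
#' Under this model the expected ratio is approximately `variance / (lam_1 *
#' lam_2)` for two clusters, i.e. a line through the origin with slope
#' `1 / (lam_1 * lam_2)` (4.5 for `lam = (2/3, 1/3)`); fit it with
#' [sweep_fit()].
#'
#' @param lam Length-2 vector of parametric means (the slope law is a
#'   two-cluster result), summing to 1.
#' @param variances Variance grid; defaults to [sweep_variances()].
#' @param reps Replicate Q matrices per variance.
#' @param i_count Individuals per matrix.
#' @param seed Optional master seed; each matrix's draw derives from it.
#' @return A tibble of class `variance_sweep` with columns `variance`,
#'   `alpha`, `replicate`, `ratio` (`length(variances) * reps` rows).
#' @examples
#' sw <- variance_sweep(reps = 5, seed = 1)
#' sweep_fit(sw)
#' @export
variance_sweep <- function(lam = c(2/3, 1/3), variances = sweep_variances(),
                           reps = 500, i_count = 50, seed = NULL) {
  stopifnot(length(lam) == 2L, reps >= 1)
  alphas <- alpha_from_variance(variances, lam[[1L]])
  run <- function() {
    purrr::map2_dfr(variances, alphas, function(v, a) {
      shape <- a * lam
      ratios <- vapply(seq_len(reps), function(r) {
        .q_ratio(.rdirichlet_rows(i_count, shape)$mat, degenerate = 0)
      }, numeric(1))
      tibble::tibble(variance = v, alpha = a, replicate = seq_len(reps),
                     ratio = ratios)
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  attr(out, "lam") <- lam
  attr(out, "i_count") <- i_count
  attr(out, "seed") <- seed
  class(out) <- c("variance_sweep", class(out))
  out
}

#' Zero-intercept regression of FST / FSTmax on Dirichlet variance
#'
#' Fits ordinary least squares of `ratio` on `variance` with the intercept
#' fixed at 0, and computes the coefficient of determination against the
#' zero-intercept model (`1 - RSS / sum(ratio^2)`). The theoretical slope is
#' `1 / (lam_1 * lam_2)`.
#'
#' @param sweep A `variance_sweep` tibble (or any data frame with `variance`
#'   and `ratio` columns).
#' @param lam Parametric means used for the theoretical slope; taken from
#'   the sweep's attribute when present.
#' @return An object of class `sweep_fit`; see [tidy.sweep_fit()] and
#'   [glance.sweep_fit()].
#' @export
sweep_fit <- function(sweep, lam = attr(sweep, "lam")) {
  fit <- stats::lm(ratio ~ 0 + variance, data = sweep)
  structure(
    list(
      fit = fit,
      slope = unname(stats::coef(fit)[["variance"]]),
      r_squared = 1 - sum(stats::resid(fit)^2) / sum(sweep$ratio^2),
      predicted_slope = if (is.null(lam)) NA_real_ else 1 / prod(lam[1:2]),
      n = nrow(sweep)
    ),
    class = "sweep_fit"
  )
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-intercept fit of FST/FSTmax on Dirichlet variance (n = %d)\n", x$n))
  cat(sprintf("  slope: %.4f (theory: %s)\n", x$slope,
              if (is.na(x$predicted_slope)) "unknown"
              else sprintf("%.4f", x$predicted_slope)))
  cat(sprintf("  zero-intercept R-squared: %.4f\n", x$r_squared))
  invisible(x)
}

#' Monte-Carlo check of the expected ratio law
#'
#' Under the Dirichlet model the expected value of FST/FSTmax is
#' approximately `1 / (alpha + 1)`, independent of the mean vector `lam` and
#' of the number of clusters. This simulates `reps` Q matrices per `alpha`
#' and reports the Monte-Carlo mean ratio, its standard error, the analytic
#' prediction, and the standardized deviation `z = (mean - predicted) / se`.
#'
#' @param alpha Vector of concentration values to check.
#' @inheritParams simulate_q
#' @param reps Replicate matrices per `alpha` (at least 2).
#' @param seed Optional master seed.
#' @return A tibble with one row per `alpha`: `alpha`, `k`, `i`, `reps`,
#'   `mean_ratio`, `predicted`, `se`, `z`.
#' @examples
#' expectation_check(alpha = c(1, 99), lam = c(2/3, 1/3), reps = 200, seed = 1)
#' @export
expectation_check <- function(alpha, lam, i_count = 50, reps = 500,
                              seed = NULL) {
  stopifnot(reps >= 2)
  run <- function() {
    purrr::map_dfr(alpha, function(a) {
      ratios <- vapply(seq_len(reps), function(r) {
        .q_ratio(.rdirichlet_rows(i_count, a * lam)$mat, degenerate = 0)
      }, numeric(1))
      se <- stats::sd(ratios) / sqrt(reps)
      tibble::tibble(
        alpha = a, k = length(lam), i = i_count, reps = reps,
        mean_ratio = mean(ratios), predicted = 1 / (a + 1), se = se,
        z = (mean(ratios) - 1 / (a + 1)) / se
      )
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Null calibration and power of the bootstrap comparison test
#'
#' Repeats the full pipeline — simulate under the Dirichlet model, bootstrap
#' two distributions of FST/FSTmax, compare with the rank-sum test —
#' `n_tests` times and returns the p-values.
#'
#' Under the null configuration (second parameters equal to the first, the
#' default) a single Q matrix is simulated per repetition and two
#' independent bootstrap distributions are drawn from it; the two
#' distributions then share one underlying sample of individuals, and the
#' p-values are approximately Uniform(0, 1). Setting `resimulate = TRUE`
#' instead draws two independent matrices from the same specification; note
#' that the rank test then compares the realized variabilities of two finite
#' samples — because the `b` bootstrap replicates enter the test as
#' independent observations, even small realized differences are declared
#' significant, and the p-values pile up near 0. Supplying a different
#' `alpha2`/`lam2`/`i_count2` always simulates the second matrix separately
#' and measures power against that alternative.
#'
#' @inheritParams simulate_q
#' @param n_tests Number of simulate-bootstrap-test repetitions.
#' @param b Bootstrap replicates per matrix.
#' @param alpha2,lam2 Dirichlet parameters of the second matrix; default to
#'   `alpha`/`lam` (the null configuration).
#' @param i_count2 Rows of the second matrix; defaults to `i_count`.
#' @param resimulate Under the null configuration only: draw a second
#'   independent matrix instead of re-bootstrapping the first (see Details).
#' @param seed Optional master seed; each repetition derives its own stream.
#' @return A tibble with columns `test` (repetition index) and `p_value`.
#' @export
calibration_experiment <- function(alpha, lam, i_count = 50, n_tests = 500,
                                   b = 200, seed = NULL, alpha2 = alpha,
                                   lam2 = lam, i_count2 = i_count,
                                   resimulate = FALSE) {
  stopifnot(n_tests >= 1, b >= 2)
  same_spec <- isTRUE(all.equal(c(alpha, i_count, lam),
                                c(alpha2, i_count2, lam2)))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seeds <- .group_seeds(seed, n_tests)
  p_values <- vapply(seq_len(n_tests), function(t) {
    withr::with_seed(seeds[[t]], {
      q1 <- .rdirichlet_rows(i_count, alpha * lam)$mat
      q2 <- if (same_spec && !resimulate) q1
        else .rdirichlet_rows(i_count2, alpha2 * lam2)$mat
      r1 <- vapply(seq_len(b), function(j) {
        .q_ratio(q1[sample.int(i_count, i_count, TRUE), , drop = FALSE],
                 degenerate = 0)
      }, numeric(1))
      r2 <- vapply(seq_len(b), function(j) {
        .q_ratio(q2[sample.int(i_count2, i_count2, TRUE), , drop = FALSE],
                 degenerate = 0)
      }, numeric(1))
      if (length(unique(c(r1, r2))) == 1L) 1 else {
        suppressWarnings(
          stats::wilcox.test(r1, r2, exact = FALSE, correct = TRUE)$p.value
        )
      }
    })
  }, numeric(1))
  tibble::tibble(test = seq_len(n_tests), p_value = p_values)
}
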