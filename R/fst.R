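#' Within-individual and total heterozygosity of a Q matrix
#'
#' The analogy treats each individual's membership vector as the allele
#' frequencies of a subpopulation. `het_within()` is the mean expected
#' heterozygosity across individuals, `1 - (1/I) * sum_i sum_k q_ki^2`;
#' `het_total()` is the expected heterozygosity of the pooled population,
#' `1 - sum_k (colmean_k)^2`. Always `0 <= het_within <= het_total <= 1`.
#'
#' @inheritParams normalize_rows
#' @return A single proportion.
#' @export
het_within <- function(q) {
  mat <- q_values(q)
  1 - sum(mat^2) / nrow(mat)
}

#' @rdname het_within
#' @export
het_total <- function(q) {
  1 - sum(colMeans(q_values(q))^2)
}

#' FST of a Q matrix
#'
#' `(H_T - H_S) / H_T`, the heterozygosity-based (GST-style) differentiation
#' of the individual membership vectors. Zero exactly when all rows are
#' identical; undefined when the matrix is monomorphic (every individual
#' fully assigned to the same single cluster, `H_T = 0`).
#'
#' @inheritParams normalize_rows
#' @return A proportion in `[0, 1]`.
#' @export
q_fst <- function(q) {
  mat <- q_values(q)
  ht <- het_total(mat)
  if (ht <= .ht_eps) {
    stop("monomorphic Q matrix: total heterozygosity is 0, FST undefined",
         call. = FALSE)
  }
  min(max((ht - het_within(mat)) / ht, 0), 1)
}

.ht_eps <- 1e-12

#' Mean membership of the highest-membership cluster
#'
#' Returns `m`, the largest column mean of the Q matrix (the analog of the
#' frequency of the most frequent allele), and `sigma1 = I * m`, the largest
#' column sum. Ties between columns are broken by the lowest column index;
#' every statistic in this package is identical under any tie choice.
#'
#' @inheritParams normalize_rows
#' @return A named list with elements `m` and `sigma1`.
#' @export
most_frequent_mean <- function(q) {
  mat <- q_values(q)
  m <- max(colMeans(mat))
  list(m = m, sigma1 = nrow(mat) * m)
}

#' Maximum FST given I individuals and mean membership M
#'
#' The constrained maximum of FST over all Q matrices with `i_count` rows
#' whose highest-membership cluster has mean membership `m`, with the number
#' of clusters unbounded. Writing `sigma1 = I * M`, the maximum is exactly 1
#' when `sigma1` is an integer in `1, ..., I - 1`, and is otherwise given by
#' a closed form in `sigma1`, its integer and fractional parts, and (for
#' `sigma1 < 1`) `J = ceiling(1 / sigma1)`. `fst_max()` evaluates the closed
#' form; `fst_max_witness()` builds the explicit maximizing Q matrix and
#' evaluates FST on it, serving as an independent cross-check (the two agree
#' to 1e-12 everywhere).
#'
#' The maximizing configuration for `1 < sigma1 < I` places `floor(sigma1)`
#' individuals fully in the top cluster, one individual split
#' `(frac(sigma1), 1 - frac(sigma1))` between the top cluster and a private
#' cluster, and every remaining individual fully in its own private cluster.
#' For `0 < sigma1 <= 1` every individual is private, with `J - 1`
#' coefficients equal to `sigma1` and one equal to `1 - (J - 1) * sigma1`.
#'
#' @param i_count Number of individuals (rows), at least 2.
#' @param m Mean membership of the highest-membership cluster, in `(0, 1)`.
#'   `m = 1` (a monomorphic total population) is an error: FST is undefined
#'   there. Vectorized over `m` in `fst_max()`.
#' @param tol Tolerance for detecting an integer `sigma1`; both adjacent
#'   branches converge to 1 at integers, so classification at the boundary
#'   is numerically harmless.
#' @return `fst_max()`: the bound, same length as `m`. `fst_max_witness()`:
#'   a list with `value` (FST of the witness) and `witness` (the maximizing
#'   `q_matrix`).
#' @examples
#' fst_max(2, 0.75)          # 1/3
#' fst_max(3, 0.5)           # 8/11
#' fst_max(2, 0.5)           # sigma1 = 1, bound is exactly 1
#' fst_max_witness(2, 0.75)$witness
#' @export
fst_max <- function(i_count, m, tol = 1e-9) {
  vapply(m, .fst_max1, numeric(1), i_count = i_count, tol = tol)
}

.fst_max1 <- function(i_count, m, tol = 1e-9) {
  .check_bound_inputs(i_count, m)
  i <- i_count
  s1 <- i * m
  r <- round(s1)
  if (abs(s1 - r) < tol && r >= 1 && r <= i - 1) return(1)
  if (s1 < 1) {
    j <- ceiling(1 / s1)
    s <- 1 - s1 * (j - 1) * (2 - j * s1)
    return(s * (i - 1) / (i - s))
  }
  fl <- floor(s1)
  fr <- s1 - fl
  num <- i * (i - 1) - s1^2 + fl - 2 * (i - 1) * fr + (2 * i - 1) * fr^2
  den <- i * (i - 1) - s1^2 + fl + fr * (2 - fr)
  num / den
}

.check_bound_inputs <- function(i_count, m) {
  if (i_count < 2) {
    stop("the FST bound requires at least 2 individuals", call. = FALSE)
  }
  if (any(m <= 0) || any(m > 1)) {
    stop("m must lie in (0, 1]", call. = FALSE)
  }
  if (any(m >= 1 - 1e-12)) {
    stop("bound undefined: m = 1 means a monomorphic total population",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname fst_max
#' @export
fst_max_witness <- function(i_count, m) {
  .check_bound_inputs(i_count, m)
  stopifnot(length(m) == 1L)
  i <- i_count
  s1 <- i * m
  if (s1 <= 1) {
    j <- ceiling(1 / s1)
    w <- matrix(0, i, i * j)
    for (r in seq_len(i)) {
      w[r, ((r - 1) * j + 1):(r * j)] <- c(rep(s1, j - 1), 1 - (j - 1) * s1)
    }
  } else {
    fl <- floor(s1)
    fr <- s1 - fl
    # columns: top cluster, then one private cluster per remaining individual
    w <- matrix(0, i, max(2L, 1L + i - fl))
    w[seq_len(fl), 1L] <- 1
    r <- fl + 1L
    ci <- 2L
    if (r <= i) {               # the single split individual
      w[r, 1L] <- fr
      w[r, ci] <- 1 - fr
      r <- r + 1L
      ci <- ci + 1L
    }
    while (r <= i) {            # fully private individuals
      w[r, ci] <- 1
      r <- r + 1L
      ci <- ci + 1L
    }
  }
  wq <- q_matrix(w, tol = 1e-9)
  list(value = q_fst(wq), witness = wq)
}

#' Normalized variability of a Q matrix: FST / FSTmax
#'
#' Assembles the full set of variability statistics for one Q matrix:
#' heterozygosities, FST, the mean membership `m` of the highest-membership
#' cluster with `sigma1 = I * m`, the constrained maximum `fst_max` given
#' `(I, m)`, and the normalized ratio `fst / fst_max`. The ratio lies in
#' `[0, 1]`: 0 exactly when all individuals have identical membership
#' vectors, 1 when the matrix is as variable as possible given `m`.
#'
#' @inheritParams normalize_rows
#' @param allow_degenerate If `TRUE`, a monomorphic matrix (`H_T = 0`)
#'   yields a row with `fst`, `fst_max` and `ratio` set to `NA` instead of
#'   an error.
#' @return A one-row tibble with columns `group`, `i`, `k`, `hs`, `ht`,
#'   `fst`, `m`, `sigma1`, `fst_max`, `ratio`.
#' @examples
#' q_stat(q_matrix(rbind(c(1, 0), c(0.5, 0.5))))  # ratio 1: maximally variable
#' @export
q_stat <- function(q, allow_degenerate = FALSE) {
  mat <- q_values(q)
  grp <- attr(q, "group")
  hs <- het_within(mat)
  ht <- het_total(mat)
  mm <- most_frequent_mean(mat)
  base <- tibble::tibble(
    group = if (is.null(grp)) NA_character_ else as.character(grp),
    i = nrow(mat), k = ncol(mat), hs = hs, ht = ht,
    m = mm$m, sigma1 = mm$sigma1
  )
  if (ht <= .ht_eps) {
    if (!allow_degenerate) {
      stop("monomorphic Q matrix: total heterozygosity is 0, ",
           "FST/FSTmax undefined", call. = FALSE)
    }
    return(dplyr::mutate(base, fst = NA_real_, fst_max = NA_real_,
                         ratio = NA_real_, .after = "ht"))
  }
  fst <- min(max((ht - hs) / ht, 0), 1)
  fmax <- .fst_max1(nrow(mat), mm$m)
  dplyr::mutate(base, fst = fst, fst_max = fmax,
                ratio = min(max(fst / fmax, 0), 1), .after = "ht")
}

# fast path used by bootstrap and simulation loops: plain matrix in,
# ratio out; monomorphic replicates map to `degenerate`
.q_ratio <- function(mat, degenerate = NA_real_) {
  cm <- colMeans(mat)
  ht <- 1 - sum(cm^2)
  if (ht <= .ht_eps) return(degenerate)
  hs <- 1 - sum(mat^2) / nrow(mat)
  fst <- min(max((ht - hs) / ht, 0), 1)
  min(max(fst / .fst_max1(nrow(mat), max(cm)), 0), 1)
}
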