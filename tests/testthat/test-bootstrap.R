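test_that("identical polymorphic rows give an all-zero bootstrap distribution", {
  q <- q_matrix(matrix(rep(c(0.5, 0.5), each = 10), 10))
  bs <- bootstrap_ratios(q, b = 100, seed = 1)
  expect_equal(nrow(bs), 100L)
  expect_true(all(bs$ratio == 0))
})

test_that("bootstrap draws are deterministic given the seed", {
  q <- simulate_q(30, alpha = 2, lam = c(2/3, 1/3), seed = 5)
  b1 <- bootstrap_ratios(q, b = 200, seed = 99)
  b2 <- bootstrap_ratios(q, b = 200, seed = 99)
  b3 <- bootstrap_ratios(q, b = 200, seed = 100)
  expect_identical(b1$ratio, b2$ratio)
  expect_false(identical(b1$ratio, b3$ratio))
  expect_true(all(b1$ratio >= 0 & b1$ratio <= 1))
  expect_equal(attr(b1, "seed"), 99)
  expect_equal(attr(b1, "b"), 200)
})

test_that("monomorphic sources error; monomorphic replicates count as 0", {
  expect_error(bootstrap_ratios(q_matrix(rbind(c(1, 0), c(1, 0))), b = 10),
               "monomorphic")
  # with one fully-assigned row, resampling it I times gives H_T = 0
  q <- q_matrix(rbind(c(1, 0), c(0.5, 0.5)))
  expect_warning(bs <- bootstrap_ratios(q, b = 400, seed = 3), "monomorphic")
  expect_gt(attr(bs, "n_degenerate"), 0)
  expect_true(all(bs$ratio >= 0 & bs$ratio <= 1))
  expect_equal(nrow(bs), 400L)  # degenerate replicates kept, not dropped
})

test_that("per-group streams are stable when groups are appended", {
  qs <- list(a = simulate_q(20, 1, c(0.5, 0.5), seed = 1),
             b = simulate_q(20, 5, c(0.5, 0.5), seed = 2),
             c = simulate_q(20, 20, c(0.5, 0.5), seed = 3))
  two <- bootstrap_groups(qs[1:2], b = 50, seed = 7)
  three <- bootstrap_groups(qs, b = 50, seed = 7)
  expect_equal(dplyr::filter(three, group %in% c("a", "b"))$ratio, two$ratio)
  expect_equal(sort(unique(three$group)), c("a", "b", "c"))
  g <- glance(three)
  expect_equal(g$b, 50)
  expect_equal(g$n_groups, 3L)
})

test_that("two-group comparison is a rank-sum test with sensible extremes", {
  mk <- function(vals, g) {
    tibble::tibble(group = g, replicate = seq_along(vals), ratio = vals)
  }
  # same values in both groups: no detectable difference
  same <- dplyr::bind_rows(mk(rep(0.25, 50), "a"), mk(rep(0.25, 50), "b"))
  res <- compare_groups(same)
  expect_equal(res$p_value, 1)
  expect_equal(res$test, "rank-sum")
  # complete separation at B = 50: overwhelming evidence
  sep <- dplyr::bind_rows(mk(rep(0, 50), "a"), mk(rep(1, 50), "b"))
  expect_lt(compare_groups(sep)$p_value, 1e-6)
  expect_error(compare_groups(mk(1:5 / 10, "a")), "at least 2 groups")
})

test_that("three groups add a Kruskal-Wallis omnibus and all pairwise rows", {
  qs <- list(x = simulate_q(25, 0.5, c(2/3, 1/3), seed = 1),
             y = simulate_q(25, 5, c(2/3, 1/3), seed = 2),
             z = simulate_q(25, 50, c(2/3, 1/3), seed = 3))
  bs <- bootstrap_groups(qs, b = 100, seed = 13)
  res <- compare_groups(bs, adjust = "bh")
  expect_equal(nrow(res), 4L)
  expect_equal(res$test, c("kruskal-wallis", rep("rank-sum", 3)))
  expect_true(is.na(res$p_adjusted[[1]]))
  pr <- dplyr::filter(res, test == "rank-sum")
  expect_equal(pr$p_adjusted,
               stats::p.adjust(pr$p_value, method = "BH"))
  none <- compare_groups(bs)
  expect_true(all(is.na(dplyr::filter(none, test == "rank-sum")$p_adjusted)))
  bonf <- compare_groups(bs, adjust = "bonferroni")
  expect_true(all(dplyr::filter(bonf, test == "rank-sum")$p_adjusted >=
                    pr$p_adjusted - 1e-15))
})

test_that("bootstrap spread shrinks as alpha grows (variance ordering)", {
  # mean bootstrap sd over several replicate matrices per alpha; a single
  # extreme-variance matrix can saturate at ratio 1, compressing its own
  # bootstrap distribution, so the ordering is about typical draws
  lam <- c(2/3, 1/3)
  mean_sd <- function(alpha) {
    mean(vapply(1:4, function(r) {
      q <- simulate_q(50, alpha = alpha, lam = lam, seed = 600 + r)
      stats::sd(suppressWarnings(
        bootstrap_ratios(q, b = 300, seed = r))$ratio)
    }, numeric(1)))
  }
  spreads <- vapply(c(21901/99, 341/99, 1/99), mean_sd, numeric(1))
  expect_lt(spreads[[1]], spreads[[2]])   # alpha1 tighter than alpha2
  expect_lt(spreads[[1]], spreads[[3]])   # alpha1 tighter than alpha4
  # location ordering: low variance near 0, extreme variance near 1
  q_low <- simulate_q(50, 21901/99, lam, seed = 605)
  q_high <- simulate_q(50, 1/99, lam, seed = 606)
  expect_lt(stats::median(bootstrap_ratios(q_low, b = 300, seed = 5)$ratio),
            0.05)
  expect_gt(stats::median(suppressWarnings(
    bootstrap_ratios(q_high, b = 300, seed = 6))$ratio), 0.9)
})
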