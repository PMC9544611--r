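test_that("heterozygosities and FST match hand values and the loop oracle", {
  cases <- list(
    rbind(c(1, 0), c(0, 1)),
    rbind(c(0.5, 0.5), c(0.5, 0.5)),
    rbind(c(1, 0), c(0.5, 0.5)),
    rbind(c(0.2, 0.3, 0.5), c(0.6, 0.1, 0.3), c(1/3, 1/3, 1/3))
  )
  for (mat in cases) {
    q <- q_matrix(mat)
    expect_equal(het_within(q), oracle_hs(mat))
    expect_equal(het_total(q), oracle_ht(mat))
    expect_equal(q_fst(q), oracle_fst(mat))
  }
  # hand-evaluated values
  expect_equal(het_within(q_matrix(cases[[1]])), 0)
  expect_equal(het_within(q_matrix(cases[[2]])), 0.5)
  expect_equal(het_within(q_matrix(cases[[3]])), 0.25)
  expect_equal(het_total(q_matrix(cases[[1]])), 0.5)
  expect_equal(het_total(q_matrix(cases[[3]])), 0.375)
  expect_equal(q_fst(q_matrix(cases[[1]])), 1)
  expect_equal(q_fst(q_matrix(cases[[3]])), 1 / 3)
})

test_that("monomorphic matrices raise a typed error everywhere", {
  mono <- q_matrix(rbind(c(1, 0), c(1, 0)))
  expect_equal(het_total(mono), 0)
  expect_error(q_fst(mono), "monomorphic")
  expect_error(q_stat(mono), "monomorphic")
  s <- q_stat(mono, allow_degenerate = TRUE)
  expect_true(is.na(s$ratio) && is.na(s$fst))
  expect_equal(s$m, 1)
})

test_that("most_frequent_mean returns the top column mean and sigma1", {
  expect_equal(most_frequent_mean(rbind(c(1, 0), c(0, 1))),
               list(m = 0.5, sigma1 = 1))
  expect_equal(most_frequent_mean(rbind(c(1, 0), c(0.5, 0.5))),
               list(m = 0.75, sigma1 = 1.5))
  big <- matrix(rep(c(2/3, 1/3), each = 50), 50)
  expect_equal(most_frequent_mean(big), list(m = 2/3, sigma1 = 100/3))
})

test_that("fst_max reproduces exact worked values", {
  expect_identical(fst_max(2, 0.5), 1)     # sigma1 = 1, integer branch
  expect_identical(fst_max(3, 2/3), 1)     # sigma1 = 2
  expect_identical(fst_max(10, 0.7), 1)    # sigma1 = 7
  expect_equal(fst_max(2, 0.75), 1/3)      # sigma1 = 1.5
  expect_equal(fst_max(2, 0.25), 1/3)      # sigma1 = 0.5, J = 2
  expect_equal(fst_max(3, 0.5), 8/11)      # sigma1 = 1.5, I = 3
  expect_error(fst_max(2, 1), "monomorphic")
  expect_error(fst_max(1, 0.5), "at least 2")
  expect_error(fst_max(3, 0), "in \\(0, 1\\]")
})

test_that("the constructive witness agrees with the closed form and is tight", {
  withr::with_seed(21, {
    for (rep in 1:40) {
      i <- sample(2:12, 1)
      m <- runif(1, 0.02, 0.98)
      if (m >= 1 - 1e-9) next
      w <- fst_max_witness(i, m)
      expect_lt(abs(w$value - fst_max(i, m)), 1e-12)
      # witness top-cluster mean reproduces M
      expect_equal(max(colMeans(as.matrix(w$witness))), m, tolerance = 1e-12)
      # the witness itself is maximally variable: ratio exactly 1
      expect_equal(q_stat(w$witness)$ratio, 1, tolerance = 1e-12)
    }
  })
  # spec'd witness shapes
  w2 <- fst_max_witness(2, 0.75)
  expect_equal(as.matrix(w2$witness), rbind(c(1, 0), c(0.5, 0.5)),
               ignore_attr = TRUE)
  w3 <- fst_max_witness(2, 0.25)
  expect_equal(as.matrix(w3$witness),
               rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5)),
               ignore_attr = TRUE)
  wi <- fst_max_witness(3, 2/3)  # integer sigma1: H_S = 0, value 1
  expect_equal(wi$value, 1)
  expect_equal(het_within(wi$witness), 0)
})

test_that("fst_max approaches 1 near integer sigma1 from both sides", {
  for (i in c(3, 5, 10)) {
    for (s1 in 1:(i - 1)) {
      expect_gt(fst_max(i, (s1 + 1e-6) / i), 0.999)
      expect_gt(fst_max(i, (s1 - 1e-6) / i), 0.999)
    }
  }
})

test_that("FST, M and the ratio are invariant to permutations and zero columns", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      mat <- random_q(sample(3:9, 1), sample(2:5, 1))
      q <- q_matrix(mat)
      base <- q_stat(q)
      perm_rows <- q_matrix(mat[sample(nrow(mat)), , drop = FALSE])
      perm_cols <- q_matrix(mat[, sample(ncol(mat)), drop = FALSE])
      zero_col <- q_matrix(cbind(mat, 0))
      for (variant in list(perm_rows, perm_cols, zero_col)) {
        v <- q_stat(variant)
        expect_equal(v$fst, base$fst)
        expect_equal(v$m, base$m)
        expect_equal(v$ratio, base$ratio)
      }
      expect_equal(q_stat(zero_col)$k, base$k + 1)
    }
  })
})

test_that("ratio is 0 exactly for identical polymorphic rows, in [0,1] otherwise", {
  withr::with_seed(41, {
    for (rep in 1:15) {
      row <- random_q(1, sample(2:5, 1))
      same <- q_matrix(row[rep(1, 6), , drop = FALSE])
      expect_equal(q_stat(same)$ratio, 0)
      mat <- random_q(sample(2:10, 1), sample(2:5, 1))
      s <- q_stat(q_matrix(mat))
      expect_gte(s$ratio, 0)
      expect_lte(s$ratio, 1)
      expect_lte(s$hs, s$ht)
      expect_gte(s$hs, 0)
      expect_lte(s$ht, 1)
      if (max(abs(sweep(mat, 2, mat[1, ]))) > 1e-12) {
        expect_gt(s$ratio, 0)
      }
    }
  })
})

test_that("fst_max bounds FST of arbitrary matrices with the same (I, M)", {
  withr::with_seed(51, {
    for (rep in 1:400) {
      mat <- random_q(sample(2:8, 1), sample(2:6, 1),
                      conc = runif(1, 0.1, 3))
      if (het_total(mat) <= 1e-12) next
      m <- most_frequent_mean(mat)$m
      if (m >= 1 - 1e-9) next
      expect_lte(q_fst(q_matrix(mat)), fst_max(nrow(mat), m) + 1e-10)
    }
  })
})
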