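# Independent brute-force oracles: literal summation of the heterozygosity
# definitions, kept free of the package's vectorized implementations.

oracle_hs <- function(mat) {
  i_count <- nrow(mat)
  acc <- 0
  for (i in seq_len(i_count)) {
    for (k in seq_len(ncol(mat))) acc <- acc + mat[i, k]^2
  }
  1 - acc / i_count
}

oracle_ht <- function(mat) {
  acc <- 0
  for (k in seq_len(ncol(mat))) {
    mean_k <- 0
    for (i in seq_len(nrow(mat))) mean_k <- mean_k + mat[i, k]
    acc <- acc + (mean_k / nrow(mat))^2
  }
  1 - acc
}

oracle_fst <- function(mat) {
  (oracle_ht(mat) - oracle_hs(mat)) / oracle_ht(mat)
}

# random valid Q matrix (rows normalized gamma variates)
random_q <- function(i_count, k_count, conc = 1) {
  g <- matrix(stats::rgamma(i_count * k_count, shape = conc), i_count)
  g / rowSums(g)
}
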