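# Shared fixtures built in code. Small cohorts keep unit tests fast; the
# acceptance suite uses the full default configuration.

small_sim_config <- function(...) {
  simulation_config(
    n_genes = 400L, n_control = 6L, n_sg1 = 8L, n_sg2 = 6L, n_sg3 = 10L,
    ...)
}

# memoised small cohort shared across tests in a file run
.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function(seed = 3L) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(small_sim_config(), seed = seed)
  .fixture_env[[key]]
}

# brute-force step-up FDR adjustment, the independent oracle for bh_adjust
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)  # rank of p[i]
    cands <- vapply(seq(rank_i, m), function(j) m * p[ord[j]] / j, numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
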