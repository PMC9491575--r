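# Shared statistical primitives: BH adjustment, exact r x c Fisher test,
# Wilcoxon rank tests. Results are returned as lightweight "tpll_test" lists
# (statistic, p_value, optional q_value, method) serializable to TSV.

test_result <- function(statistic, p_value, method, q_value = NA_real_) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 q_value = q_value, method = method),
            class = "tpll_test")
}

#' @export
print.tpll_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment (q-values): the adjusted value for
#' the i-th smallest p is `min_{j >= i} (m * p_(j) / j)` capped at 1, which is
#' order-preserving in p.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# log multinomial-margin probability of a contingency table under
# independence with fixed margins
log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact Fisher test for r x c contingency tables
#'
#' Enumerates (depth-first) all nonnegative integer tables with the observed
#' margins and sums the probability of those no more probable than the
#' observed table (probability-mass criterion, the classical two-sided
#' definition). A relative tolerance of 1e-7 guards the floating-point
#' comparison. For 2 x 2 tables a one-sided (enrichment) alternative is also
#' available via the hypergeometric tail.
#'
#' @param tab matrix of nonnegative integer counts.
#' @param alternative `"two.sided"` (any r x c) or `"greater"` (2 x 2 only;
#'   over-representation of the top-left cell).
#' @return a `tpll_test` result (statistic = observed table probability).
#' @export
fisher_exact_rxc <- function(tab, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table cells must be nonnegative integers")
  storage.mode(tab) <- "double"
  n <- sum(tab)
  if (alternative == "greater") {
    if (!all(dim(tab) == c(2L, 2L)))
      stop("one-sided test is defined for 2 x 2 tables only")
    k <- tab[1, 1]
    p <- phyper(k - 1, rowSums(tab)[1], rowSums(tab)[2], colSums(tab)[1],
                lower.tail = FALSE)
    return(test_result(k, min(1, p), "Fisher exact (one-sided, 2x2)"))
  }
  if (n > 200) stop("exact enumeration infeasible: table total exceeds 200")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("all row and column margins must be positive")
  lp_obs <- log_table_prob(tab)
  # DFS over tables with fixed margins; rows filled one by one, each row a
  # bounded composition of its margin; last row determined by column slack.
  nr <- nrow(tab); nc <- ncol(tab)
  acc <- 0
  row_compositions <- function(total, caps) {
    if (length(caps) == 1L) {
      if (total <= caps) return(list(total)) else return(list())
    }
    out <- list()
    for (v in 0:min(total, caps[1L])) {
      for (rest in row_compositions(total - v, caps[-1L]))
        out[[length(out) + 1L]] <- c(v, rest)
    }
    out
  }
  # iterative DFS with explicit stack of (row index, remaining col margins,
  # partial log "cell" term sum); the last row is forced by the column slack
  base_lp <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  tol <- 1e-7
  stack <- list(list(i = 1L, col_left = cs, cell_lp = 0))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (fr$i == nr) {
      lp <- base_lp + fr$cell_lp - sum(lgamma(fr$col_left + 1))
      if (lp <= lp_obs + tol * abs(lp_obs) + 1e-12) acc <- acc + exp(lp)
    } else {
      for (comp in row_compositions(rs[fr$i], fr$col_left)) {
        stack[[length(stack) + 1L]] <- list(
          i = fr$i + 1L,
          col_left = fr$col_left - comp,
          cell_lp = fr$cell_lp - sum(lgamma(comp + 1)))
      }
    }
  }
  test_result(exp(lp_obs), min(1, acc), "Fisher exact (r x c enumeration)")
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact null distribution when the combined sample size is at most
#' `exact_below` and there are no ties; otherwise the normal approximation
#' with average ranks, tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative as in [stats::wilcox.test()].
#' @param exact_below combined-n threshold for the exact distribution.
#' @return a `tpll_test` result (statistic = rank-sum W of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided", exact_below = 50L) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  exact <- (length(x) + length(y)) <= exact_below && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                     exact = exact, correct = TRUE))
  test_result(wt$statistic, wt$p.value, "Wilcoxon rank sum")
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (the standard convention). When all
#' differences are zero the test is degenerate and p = 1 is returned by
#' convention.
#'
#' @param d vector of paired differences.
#' @param alternative as in [stats::wilcox.test()].
#' @param exact_below n threshold for the exact distribution.
#' @return a `tpll_test` result.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "two.sided", exact_below = 50L) {
  if (!length(d)) stop("input must be non-empty")
  d <- d[d != 0]
  if (!length(d))
    return(test_result(0, 1, "Wilcoxon signed rank (degenerate: all zero)"))
  exact <- length(d) <= exact_below && !anyDuplicated(abs(d))
  wt <- suppressWarnings(wilcox.test(d, alternative = alternative,
                                     exact = exact, correct = TRUE))
  test_result(wt$statistic, wt$p.value, "Wilcoxon signed rank")
}
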