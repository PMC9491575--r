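# Lasso solution path (LARS homotopy with drops) and the covariance test
# for the significance of predictors entering the path. Columns of the
# design matrix are assumed centered and scaled to unit L2 norm, and the
# response centered, so that the path knots are the usual equicorrelation
# break points lambda_1 > lambda_2 > ...

# full lasso path bookkeeping; returns, per entry event, the entering
# variable, its knot lambda, the next knot lambda (entry or drop), and the
# active set/signs immediately before and after the entry
lasso_lars_path <- function(X, y, max_steps = 6L, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  c0 <- drop(crossprod(X, y))
  lam <- max(abs(c0))
  if (lam < tol) return(list(entries = list(), ok = TRUE))
  A <- integer(0); s <- numeric(0)
  entries <- list()
  j_enter <- which.max(abs(c0))
  repeat {
    # record entry of j_enter at current lam
    A_before <- A; s_before <- s
    A <- c(A, j_enter); s <- c(s, sign(c0[j_enter] - 0)) # sign set below
    # recompute sign of correlation at entry for correctness
    s[length(s)] <- entry_sign(X, y, A_before, s_before, j_enter, lam, tol)
    ent <- list(var = j_enter, lambda = lam, A_before = A_before,
                s_before = s_before, A_after = A, s_after = s,
                lambda_next = 0)
    XA <- X[, A, drop = FALSE]
    G <- crossprod(XA)
    Ginv <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(Ginv)) return(list(entries = entries, ok = FALSE))
    b0 <- drop(Ginv %*% crossprod(XA, y))
    b1 <- drop(Ginv %*% s)
    u0 <- drop(XA %*% b0); u1 <- drop(XA %*% b1)
    rho <- c0 - drop(crossprod(X, u0))
    theta <- drop(crossprod(X, u1))
    inactive <- setdiff(seq_len(p), A)
    lam_entry <- -Inf; j_next <- NA_integer_
    if (length(inactive)) {
      c1 <- rho[inactive] / (1 - theta[inactive])
      c2 <- -rho[inactive] / (1 + theta[inactive])
      cand <- pmax(ifelse(is.finite(c1) & c1 > tol & c1 < lam - tol, c1, -Inf),
                   ifelse(is.finite(c2) & c2 > tol & c2 < lam - tol, c2, -Inf))
      bi <- which.max(cand)
      if (is.finite(cand[bi])) { lam_entry <- cand[bi]; j_next <- inactive[bi] }
    }
    lam_drop <- -Inf; k_drop <- NA_integer_
    for (k in seq_along(A)) {
      if (abs(b1[k]) > tol) {
        cand <- b0[k] / b1[k]
        if (cand > tol && cand < lam - tol && cand > lam_drop) {
          lam_drop <- cand; k_drop <- k
        }
      }
    }
    lam_next <- max(lam_entry, lam_drop, 0)
    ent$lambda_next <- lam_next
    entries[[length(entries) + 1L]] <- ent
    if (length(entries) >= max_steps || lam_next <= 0 ||
        length(A) >= min(n - 1L, p)) break
    if (lam_drop >= lam_entry && is.finite(lam_drop) && !is.na(k_drop) &&
        lam_drop > 0) {
      # drop event: variable leaves; continue path from lam_drop without a
      # new entry record
      lam <- lam_drop
      A <- A[-k_drop]; s <- s[-k_drop]
      nxt <- next_entry_after_drop(X, y, c0, A, s, lam, p, tol)
      if (is.null(nxt)) break
      lam <- nxt$lambda; j_enter <- nxt$var
      # amend previous entry's lambda_next to the true next knot (the drop)
      entries[[length(entries)]]$lambda_next <- lam_drop
      next
    }
    if (!is.finite(lam_entry) || is.na(j_next)) break
    lam <- lam_entry
    j_enter <- j_next
  }
  list(entries = entries, ok = TRUE)
}

entry_sign <- function(X, y, A_before, s_before, j, lam, tol) {
  if (!length(A_before)) return(sign(sum(X[, j] * y)))
  XA <- X[, A_before, drop = FALSE]
  G <- crossprod(XA)
  Ginv <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(Ginv)) return(1)
  beta <- drop(Ginv %*% (crossprod(XA, y) - lam * s_before))
  sign(sum(X[, j] * (y - XA %*% beta)))
}

next_entry_after_drop <- function(X, y, c0, A, s, lam, p, tol) {
  if (!length(A)) {
    j <- which.max(abs(c0))
    return(list(var = j, lambda = lam))
  }
  XA <- X[, A, drop = FALSE]
  G <- crossprod(XA)
  Ginv <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(Ginv)) return(NULL)
  b0 <- drop(Ginv %*% crossprod(XA, y))
  b1 <- drop(Ginv %*% s)
  rho <- c0 - drop(crossprod(X, XA %*% b0))
  theta <- drop(crossprod(X, XA %*% b1))
  inactive <- setdiff(seq_len(p), A)
  c1 <- rho[inactive] / (1 - theta[inactive])
  c2 <- -rho[inactive] / (1 + theta[inactive])
  cand <- pmax(ifelse(is.finite(c1) & c1 > tol & c1 <= lam + tol, c1, -Inf),
               ifelse(is.finite(c2) & c2 > tol & c2 <= lam + tol, c2, -Inf))
  bi <- which.max(cand)
  if (!is.finite(cand[bi])) return(NULL)
  list(var = inactive[bi], lambda = cand[bi])
}

# lasso solution for a fixed active set / signs at penalty lam
beta_at <- function(X, y, A, s, lam) {
  if (!length(A)) return(numeric(0))
  XA <- X[, A, drop = FALSE]
  drop(solve(crossprod(XA), crossprod(XA, y) - lam * s))
}

#' Covariance test p-values along a lasso path
#'
#' For the k-th predictor entering the lasso path at knot `lambda_k`, the
#' covariance test statistic is
#' `T_k = (<y, X b(lambda_{k+1})> - <y, X_A b_A(lambda_{k+1})>) / sigma2`,
#' where `b` is the lasso solution including the new predictor, `b_A` the
#' lasso solution restricted to the previously active set `A`, both
#' evaluated at the next knot. Under the null that all signal is already
#' captured by `A`, `T_k` is asymptotically Exp(1), giving `p = exp(-T_k)`.
#'
#' @param X design matrix; columns are centered and scaled to unit L2 norm
#'   internally.
#' @param y response; centered internally.
#' @param sigma2 error variance; if `NULL`, estimated by
#'   [estimate_sigma2()].
#' @param max_steps maximal number of path entries tested.
#' @return data.frame: `var` (column index), `predictor` (column name),
#'   `order`, `lambda`, `T`, `p`; attribute `sigma2`; zero rows if the path
#'   is empty or fails (intercept-only model).
#' @export
covariance_test_path <- function(X, y, sigma2 = NULL, max_steps = 6L) {
  X <- as.matrix(X)
  y <- y - mean(y)
  ctr <- colMeans(X)
  Xc <- X - rep(ctr, each = nrow(X))
  nrm <- sqrt(colSums(Xc^2))
  keep <- nrm > 1e-12
  Xn <- Xc[, keep, drop = FALSE] / rep(nrm[keep], each = nrow(X))
  core <- cov_test_core(Xn, y, sigma2 = sigma2, max_steps = max_steps)
  var_idx <- which(keep)[core$var]
  out <- data.frame(var = var_idx,
                    predictor = colnames(X)[var_idx] %||%
                      rep(NA_character_, length(var_idx)),
                    order = seq_along(var_idx), lambda = core$lambda,
                    T = core$T, p = core$p, stringsAsFactors = FALSE)
  structure(out, sigma2 = core$sigma2)
}

# lean engine operating on a pre-standardized design (centered, unit-norm
# columns) and centered response; returns parallel vectors
cov_test_core <- function(Xn, y, sigma2 = NULL, max_steps = 6L) {
  path <- lasso_lars_path(Xn, y, max_steps = max_steps)
  nk <- length(path$entries)
  if (!nk) return(list(var = integer(0), lambda = numeric(0),
                       T = numeric(0), p = numeric(0), sigma2 = sigma2))
  if (is.null(sigma2)) {
    last <- path$entries[[nk]]
    sigma2 <- estimate_sigma2(Xn, y, active = last$A_after)
  }
  Tv <- lambda <- numeric(nk); var_idx <- integer(nk)
  for (k in seq_len(nk)) {
    e <- path$entries[[k]]
    fit_full <- if (length(e$A_after))
      drop(Xn[, e$A_after, drop = FALSE] %*%
             beta_at(Xn, y, e$A_after, e$s_after, e$lambda_next)) else 0
    fit_red <- if (length(e$A_before))
      drop(Xn[, e$A_before, drop = FALSE] %*%
             beta_at(Xn, y, e$A_before, e$s_before, e$lambda_next)) else 0
    Tv[k] <- (sum(y * fit_full) - sum(y * fit_red)) / sigma2
    lambda[k] <- e$lambda
    var_idx[k] <- e$var
  }
  list(var = var_idx, lambda = lambda, T = Tv,
       p = pmin(1, exp(-pmax(Tv, 0))), sigma2 = sigma2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Error-variance estimate for the covariance test
#'
#' With fewer predictors than `n - 10`, the residual variance of the full
#' ordinary-least-squares fit (the standard choice when it exists). With
#' wide designs, the degrees-of-freedom-corrected residual variance of a
#' least-squares refit on the active set at the last computed lasso knot.
#'
#' @param X design matrix (centered columns).
#' @param y centered response.
#' @param active column indices of the last active set (used when p >= n -
#'   10).
#' @return scalar variance estimate.
#' @export
estimate_sigma2 <- function(X, y, active = NULL) {
  n <- nrow(X); p <- ncol(X)
  if (p <= n - 10L) {
    fit <- lm.fit(cbind(1, X), y)
    return(sum(fit$residuals^2) / max(1L, n - p - 1L))
  }
  if (!length(active)) return(var(y))
  XA <- X[, active, drop = FALSE]
  fit <- lm.fit(cbind(1, XA), y)
  sum(fit$residuals^2) / max(1L, n - length(active) - 1L)
}
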