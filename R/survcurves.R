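# Survival comparison across subgroups and sexes: Kaplan-Meier
# product-limit estimation and the log-rank test, backed by the survival
# package. Event status follows the cohort convention: "died" is the event,
# "censored" (alive with disease at last follow-up) is non-informative
# censoring.

surv_event <- function(status) {
  if (is.numeric(status)) return(as.integer(status != 0))
  if (!all(status %in% c("died", "censored")))
    stop("status must be 'died' or 'censored'")
  as.integer(status == "died")
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' deaths ranked before censorings at tied times (the standard discrete
#' convention). With no censoring this reduces to the complement of the
#' empirical distribution function.
#'
#' @param time follow-up times (>= 0), days.
#' @param status `"died"` / `"censored"` (or 0/1 with 1 = event).
#' @return data.frame: time, n_risk, n_event, n_censor, surv; attribute
#'   `all_censored` flags the degenerate no-event case (S identically 1).
#' @export
km_estimate <- function(time, status) {
  if (any(time < 0)) stop("times must be >= 0")
  ev <- surv_event(status)
  fit <- survival::survfit(survival::Surv(time, ev) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "all_censored") <- sum(ev) == 0
  out
}

#' Log-rank test across groups
#'
#' Observed-versus-expected chi-square over the pooled event times with
#' (number of groups - 1) degrees of freedom.
#'
#' @param time follow-up times.
#' @param status `"died"` / `"censored"` (or 0/1).
#' @param group group label per subject (>= 2 non-empty groups; at least
#'   one event overall).
#' @return a `tpll_test` result with `df` attached.
#' @export
logrank_test <- function(time, status, group) {
  ev <- surv_event(status)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) == 0L)) stop("group with zero subjects")
  if (sum(ev) == 0L) stop("need at least one event")
  sd <- survival::survdiff(survival::Surv(time, ev) ~ group)
  df <- nlevels(group) - 1L
  res <- test_result(sd$chisq, pchisq(sd$chisq, df, lower.tail = FALSE),
                     "log-rank")
  res$df <- df
  res
}
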