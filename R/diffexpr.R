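# Subgroup-versus-control differential expression: a joint one-way linear
# model per gene (control baseline, one coefficient per tumor subgroup, a
# single pooled residual variance), empirical-Bayes variance moderation and
# moderated t-statistics with BH q-values.

#' Fit per-gene one-way group models
#'
#' For each gene a one-way linear model over the groups
#' (control, SG1, SG2, SG3, ...) is fitted jointly: the coefficient of a
#' subgroup is its mean minus the control mean, and the pooled residual
#' variance has `n - (number of groups)` degrees of freedom. Genes with zero
#' residual variance are flagged (`zero_variance`).
#'
#' @param x expression matrix (genes x samples).
#' @param samples sample table with `group`; `control_label` names the
#'   baseline group.
#' @param control_label baseline group label.
#' @return list with `coefficients` (gene x subgroup log2 fold changes),
#'   `s2` (pooled residual variance), `df` (residual df, scalar),
#'   `stdev_unscaled` (per-contrast sqrt(1/n_g + 1/n_control)),
#'   `group_sizes`, `zero_variance`.
#' @export
fit_group_models <- function(x, samples, control_label = "control") {
  vals <- unclass(x)
  grp <- samples$group[match(colnames(vals), samples$sample_id)]
  if (anyNA(grp)) stop("samples missing from metadata table")
  if (!control_label %in% grp) stop("control group not present")
  tab <- table(grp)
  if (any(tab < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  levels <- c(control_label, sort(setdiff(unique(grp), control_label)))
  means <- vapply(levels, function(g)
    rowMeans(vals[, grp == g, drop = FALSE]), numeric(nrow(vals)))
  rss <- rowSums((vals - means[, match(grp, levels)])^2)
  df <- ncol(vals) - length(levels)
  s2 <- rss / df
  contrasts <- levels[-1L]
  beta <- means[, contrasts, drop = FALSE] - means[, control_label]
  su <- sqrt(1 / tab[contrasts] + 1 / tab[control_label])
  list(coefficients = beta, s2 = s2, df = df,
       stdev_unscaled = setNames(as.numeric(su), contrasts),
       group_sizes = tab, zero_variance = s2 == 0)
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Shrinks gene-wise residual variances toward a common prior by fitting a
#' scaled inverse-chi-square prior (prior df `d0`, prior variance `s0²`) to
#' the observed variances via moment matching on log s² (digamma/trigamma
#' relations), then forms the posterior variance
#' `s̃² = (d0 s0² + d s²) / (d0 + d)`. When all variances coincide the
#' no-dispersion branch `d0 = Inf`, `s̃² = s0² = s²` applies. Genes flagged
#' as zero-variance are excluded from estimation and keep `s̃² = 0`.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param zero_variance logical flag per gene (excluded from moderation).
#' @return list with `d0` (prior df), `s0_2` (prior variance), `s2_post`.
#' @export
moderate_variances <- function(s2, df, zero_variance = s2 == 0) {
  ok <- !zero_variance
  if (sum(ok) < 10L) stop("need at least 10 genes with positive variance")
  if (all(abs(s2[ok] - s2[ok][1]) < 1e-15)) {
    s2_post <- s2
    return(list(d0 = Inf, s0_2 = s2[ok][1], s2_post = s2_post))
  }
  sq <- limma::squeezeVar(s2[ok], df = df)
  s2_post <- numeric(length(s2))
  s2_post[ok] <- sq$var.post
  list(d0 = sq$df.prior, s0_2 = sq$var.prior, s2_post = s2_post)
}

#' Moderated t-tests for all subgroup-versus-control contrasts
#'
#' t = beta / (s_post * stdev_unscaled) with `d0 + d` degrees of freedom;
#' two-sided p-values; q-values by BH adjustment over all genes within each
#' contrast. Genes with q below the cutoff form the DE set of a contrast,
#' split by the sign of the log2 fold change into up/down.
#'
#' @param fit result of [fit_group_models()].
#' @param moderation result of [moderate_variances()]; pass `d0 = 0` inside
#'   to recover the classical pooled t-test.
#' @param q_cutoff FDR cutoff defining the DE sets (default 0.05).
#' @return list with `tables` (per-contrast data.frame: gene, log2fc, t, p,
#'   q, direction), `de_sets` and `de_up` / `de_down` gene-id lists,
#'   `d0`, `df_total`.
#' @export
moderated_t_test <- function(fit, moderation = moderate_variances(fit$s2, fit$df),
                             q_cutoff = 0.05) {
  d0 <- moderation$d0
  df_total <- if (is.finite(d0)) d0 + fit$df else Inf
  s_post <- sqrt(moderation$s2_post)
  genes <- rownames(fit$coefficients)
  tables <- lapply(colnames(fit$coefficients), function(ct) {
    beta <- fit$coefficients[, ct]
    se <- s_post * fit$stdev_unscaled[ct]
    t <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
    p <- if (is.finite(df_total)) 2 * pt(-abs(t), df = df_total)
         else 2 * pnorm(-abs(t))
    q <- bh_adjust(p)
    data.frame(gene = genes, log2fc = beta, t = t, p = p, q = q,
               direction = ifelse(q <= q_cutoff & beta > 0, "up",
                           ifelse(q <= q_cutoff & beta < 0, "down", "unchanged")),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(tables) <- colnames(fit$coefficients)
  de_sets <- lapply(tables, function(tb) tb$gene[tb$direction != "unchanged"])
  list(tables = tables,
       de_sets = de_sets,
       de_up = lapply(tables, function(tb) tb$gene[tb$direction == "up"]),
       de_down = lapply(tables, function(tb) tb$gene[tb$direction == "down"]),
       d0 = d0, df_total = df_total, q_cutoff = q_cutoff)
}

#' Run the full differential-expression workflow
#'
#' Convenience wrapper: [fit_group_models()], [moderate_variances()],
#' [moderated_t_test()].
#'
#' @inheritParams fit_group_models
#' @inheritParams moderated_t_test
#' @return as [moderated_t_test()], plus `fit` and `moderation`.
#' @export
run_diffexpr <- function(x, samples, control_label = "control", q_cutoff = 0.05) {
  fit <- fit_group_models(x, samples, control_label)
  moderation <- moderate_variances(fit$s2, fit$df, fit$zero_variance)
  res <- moderated_t_test(fit, moderation, q_cutoff)
  res$fit <- fit
  res$moderation <- moderation
  res
}

#' Venn region counts for three gene sets
#'
#' The seven disjoint region counts of a three-set Venn diagram plus the
#' union size.
#'
#' @param sets named list of three character vectors.
#' @return named numeric vector: `a_only`, `b_only`, `c_only`, `ab`, `ac`,
#'   `bc`, `abc`, `union` (names a/b/c follow the input order).
#' @export
venn3 <- function(sets) {
  stopifnot(length(sets) == 3L)
  a <- unique(sets[[1L]]); b <- unique(sets[[2L]]); c <- unique(sets[[3L]])
  abc <- intersect(intersect(a, b), c)
  ab <- setdiff(intersect(a, b), abc)
  ac <- setdiff(intersect(a, c), abc)
  bc <- setdiff(intersect(b, c), abc)
  c(a_only = length(setdiff(a, union(b, c))),
    b_only = length(setdiff(b, union(a, c))),
    c_only = length(setdiff(c, union(a, b))),
    ab = length(ab), ac = length(ac), bc = length(bc),
    abc = length(abc), union = length(union(union(a, b), c)))
}

#' Venn overlaps of differential-expression sets across subgroups
#'
#' Region counts for the combined DE sets and separately for the up- and
#' down-regulated sets of the three subgroups.
#'
#' @param de result of [moderated_t_test()] / [run_diffexpr()] with three
#'   contrasts.
#' @return list of three named vectors: `combined`, `up`, `down`.
#' @export
de_overlaps <- function(de) {
  stopifnot(length(de$de_sets) == 3L)
  list(combined = venn3(de$de_sets), up = venn3(de$de_up),
       down = venn3(de$de_down))
}
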