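make_groups <- function(sizes) {
  data.frame(sample_id = paste0("s", seq_len(sum(sizes))),
             group = rep(names(sizes), sizes), stringsAsFactors = FALSE)
}

test_that("group models recover noiseless means exactly", {
  sizes <- c(control = 3, SG1 = 3, SG2 = 2, SG3 = 2)
  v <- rbind(gA = rep(c(1, 3.5, 1, 1), sizes),
             gB = rep(2, 10))
  colnames(v) <- paste0("s", 1:10)
  fit <- fit_group_models(expression_matrix(v), make_groups(sizes))
  expect_equal(unname(fit$coefficients["gA", ]), c(2.5, 0, 0))
  expect_equal(unname(fit$s2[["gA"]]), 0)
  expect_true(all(fit$zero_variance))
  expect_error(fit_group_models(expression_matrix(v),
                                make_groups(c(control = 1, SG1 = 9))),
               "fewer than 2")
})

test_that("group models equal a per-gene OLS oracle", {
  co <- small_cohort()
  v <- unclass(co$expr)[1:40, ]
  fit <- fit_group_models(expression_matrix(v), co$samples)
  grp <- factor(co$samples$group[match(colnames(v), co$samples$sample_id)],
                levels = c("control", "SG1", "SG2", "SG3"))
  for (g in sample(rownames(v), 10)) {
    lmfit <- lm(v[g, ] ~ grp)
    expect_equal(unname(fit$coefficients[g, ]),
                 unname(coef(lmfit)[-1]), tolerance = 1e-10)
    expect_equal(unname(fit$s2[[g]]),
                 sum(residuals(lmfit)^2) / lmfit$df.residual,
                 tolerance = 1e-10)
    expect_identical(fit$df, lmfit$df.residual)
  }
})

test_that("variance moderation handles the degenerate and recovery cases", {
  expect_error(moderate_variances(rep(1, 5), 10), "10 genes")
  mod <- moderate_variances(rep(2, 50), 10)
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(2, 50))

  # scaled inverse-chi-square prior recovery: d0 = 4, s0^2 = 2
  set.seed(13)
  d0 <- 4; s0 <- 2; d <- 10
  sigma2 <- s0 * d0 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, d) / d
  mod2 <- moderate_variances(s2, d)
  expect_lt(abs(mod2$d0 - d0) / d0, 0.25)
  expect_lt(abs(mod2$s0_2 - s0) / s0, 0.10)
  # posterior variance lies between the observed and the prior
  lo <- pmin(s2, mod2$s0_2); hi <- pmax(s2, mod2$s0_2)
  expect_true(all(mod2$s2_post >= lo - 1e-12 & mod2$s2_post <= hi + 1e-12))
})

test_that("moderated t reduces to the classical pooled t when d0 = 0", {
  set.seed(3)
  sizes <- c(control = 6, SG1 = 7)
  v <- matrix(rnorm(40 * 13, 5), 40, 13,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:13)))
  fit <- fit_group_models(expression_matrix(v), make_groups(sizes))
  res <- moderated_t_test(fit, moderation = list(d0 = 0, s0_2 = 1,
                                                 s2_post = fit$s2))
  for (g in c("g1", "g17", "g40")) {
    tt <- t.test(v[g, 7:13], v[g, 1:6], var.equal = TRUE)
    row <- res$tables$SG1[res$tables$SG1$gene == g, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("full workflow agrees with the reference moderated-t pipeline", {
  co <- small_cohort()
  v <- unclass(co$expr)[1:150, ]
  res <- run_diffexpr(expression_matrix(v), co$samples)
  grp <- factor(co$samples$group[match(colnames(v), co$samples$sample_id)],
                levels = c("control", "SG1", "SG2", "SG3"))
  design <- model.matrix(~grp)
  lfit <- limma::eBayes(limma::lmFit(v, design))
  for (sg in c("SG1", "SG2", "SG3")) {
    i <- match(res$tables[[sg]]$gene, rownames(v))
    expect_equal(res$tables[[sg]]$log2fc,
                 unname(lfit$coefficients[i, paste0("grp", sg)]),
                 tolerance = 1e-8)
    expect_equal(res$tables[[sg]]$t,
                 unname(lfit$t[i, paste0("grp", sg)]), tolerance = 1e-6)
    expect_equal(res$tables[[sg]]$p,
                 unname(lfit$p.value[i, paste0("grp", sg)]), tolerance = 1e-6)
  }
})

test_that("moderated p-values are uniform under a global null", {
  set.seed(19)
  sizes <- c(control = 5, SG1 = 5, SG2 = 5, SG3 = 5)
  v <- matrix(rnorm(4000 * 20), 4000, 20,
              dimnames = list(paste0("g", 1:4000), paste0("s", 1:20)))
  res <- run_diffexpr(expression_matrix(v), make_groups(sizes))
  ks <- ks.test(res$tables$SG2$p, "punif")
  expect_gt(ks$p.value, 0.01)
  # |t| monotone in |beta| at fixed variance
  tb <- res$tables$SG1
  o <- order(abs(tb$log2fc))
  sel <- res$moderation$s2_post > 0
  expect_gt(cor(abs(tb$log2fc), abs(tb$t), method = "spearman"), 0.95)
})

test_that("Venn region counts match brute-force set algebra", {
  expect_equal(unname(venn3(list(c("A"), c("B"), c("C")))),
               c(1, 1, 1, 0, 0, 0, 0, 3))
  s <- c("x", "y", "z")
  expect_equal(unname(venn3(list(s, s, s))["abc"]), 3, ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:20) {
    uni <- paste0("g", 1:30)
    sets <- lapply(1:3, function(j) sample(uni, sample(0:20, 1)))
    v <- venn3(sets)
    a <- sets[[1]]; b <- sets[[2]]; c_ <- sets[[3]]
    expect_equal(unname(v["abc"]), length(Reduce(intersect, sets)))
    expect_equal(unname(v["a_only"]), length(setdiff(a, union(b, c_))))
    expect_equal(unname(v["union"]), length(Reduce(union, sets)))
    expect_equal(sum(v[1:7]), unname(v["union"]))
  }
})
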