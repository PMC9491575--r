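test_that("a planted single-predictor model is recovered with refit", {
  set.seed(2)
  n <- 50
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(paste0("s", 1:n), paste0("V", 1:21)))
  y <- 3 * X[, 1] + rnorm(n, 0, 0.1)
  ct <- covariance_test_path(X, y)
  expect_identical(ct$predictor[1], "V1")
  expect_lt(ct$p[1], 1e-4)

  # via the gene-model surface with its q-cutoff refit
  expr <- expression_matrix(rbind(target = y + 8, t(X) + 8))
  m <- fit_gene_model("target", expr, cn = NULL,
                      train_ids = colnames(expr), q_cutoff = 0.05)
  expect_true("V1" %in% names(m$coefficients))
  expect_equal(unname(m$coefficients["V1"]), 3, tolerance = 0.1)
})

test_that("a purely cis-driven gene keeps only its copy-number term", {
  set.seed(4)
  n <- 40
  cn_row <- rnorm(n)
  decoys <- matrix(rnorm(n * 15) + 8, 15, n,
                   dimnames = list(paste0("d", 1:15), paste0("s", 1:n)))
  expr <- expression_matrix(rbind(target = cn_row + 8, decoys))
  cn <- matrix(cn_row, 1, n, dimnames = list("target", paste0("s", 1:n)))
  m <- fit_gene_model("target", expr, cn, train_ids = colnames(expr),
                      q_cutoff = 0.01)
  expect_identical(names(m$coefficients), ".own_cn")
  expect_equal(unname(m$coefficients[1]), 1, tolerance = 0.05)
})

test_that("first-knot covariance statistic is near Exp(1) under the null", {
  set.seed(17)
  T1 <- replicate(300, {
    X <- matrix(rnorm(60 * 2000), 60, 2000)
    y <- rnorm(60)
    covariance_test_path(X, y, sigma2 = sum((y - mean(y))^2) / 60,
                         max_steps = 2)$T[1]
  })
  expect_lt(abs(mean(T1) - 1), 0.2)
  expect_lt(abs(median(T1) - log(2)), 0.15)
})

test_that("ensemble respects split sizes, determinism, and degeneracy", {
  co <- small_cohort()
  de <- run_diffexpr(co$expr, co$samples)
  uni <- head(Reduce(union, de$de_sets), 40)
  tum <- co$samples$sample_id[co$samples$group != "control"]
  # 53-like cohort: train two thirds
  expr53 <- expression_matrix(unclass(co$expr)[uni, tum[1:24]])
  ens <- infer_ensemble(expr53, NULL, n_runs = 2, seed = 5)
  expect_true(all(vapply(ens$runs, function(r) length(r$train), 0L) == 16L))
  expect_true(all(vapply(ens$runs, function(r) length(r$test), 0L) == 8L))

  ens2 <- infer_ensemble(expr53, NULL, n_runs = 2, seed = 5)
  expect_identical(lapply(ens$runs, `[[`, "links"),
                   lapply(ens2$runs, `[[`, "links"))

  # single run: downstream operations still defined
  ens1 <- infer_ensemble(expr53, NULL, n_runs = 1, seed = 5)
  cons1 <- consensus_and_modules(ens1, support_min = 1)
  expect_true(is.data.frame(cons1$links))
  q1 <- prediction_quality(ens1, expr53, NULL)
  expect_length(q1, length(uni))

  expect_warning(infer_ensemble(expr53, NULL, n_runs = 1,
                                train_fraction = 0.95, seed = 1),
                 "train_fraction")
})

test_that("consensus and module rules reproduce hand-derived toys", {
  toy <- data.frame(predictor = c("A", "B", "C", "D"),
                    target = c("B", "C", "A", "E"),
                    support = c(80L, 76L, 90L, 74L))
  res <- consensus_and_modules(toy, support_min = 75)
  expect_setequal(paste(res$links$predictor, res$links$target),
                  c("A B", "B C", "C A"))
  expect_setequal(res$modules$gene, c("A", "B", "C"))
  expect_identical(unique(res$modules$module), 1L)

  # chain: ends have a single link each, pruning dissolves the module
  chain <- data.frame(predictor = c("A", "B"), target = c("B", "C"),
                      support = c(80L, 80L))
  expect_identical(nrow(consensus_and_modules(chain,
                                              support_min = 75)$modules), 0L)

  # consensus shrinks monotonically with the support threshold
  set.seed(3)
  big <- data.frame(predictor = sample(LETTERS[1:8], 30, TRUE),
                    target = sample(LETTERS[1:8], 30, TRUE),
                    support = sample(50:100, 30, TRUE))
  big <- big[big$predictor != big$target, ]
  n_prev <- Inf
  for (sm in c(60, 75, 90)) {
    n_now <- nrow(consensus_and_modules(big, support_min = sm)$links)
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("degree-preserving rewiring preserves degrees exactly", {
  set.seed(6)
  links <- data.frame(
    predictor = c("A", "A", "B", "C", "D", ".own_cn"),
    target = c("B", "C", "D", "D", "A", "E"),
    q = 0.001, beta = 1, stringsAsFactors = FALSE)
  rl <- tpllsubtyper:::rewire_links(links)
  expect_identical(sort(table(rl$predictor)), sort(table(links$predictor)))
  expect_identical(sort(table(rl$target)), sort(table(links$target)))
  expect_true(all(rl$predictor != rl$target))
  # own-CN links stay attached to their target
  expect_identical(rl$target[rl$predictor == ".own_cn"], "E")
})

test_that("module expression annotation encodes significance and sign", {
  modules <- data.frame(module = 1L, gene = c("g1", "g2", "g3"))
  de <- list(tables = list(
    SG1 = data.frame(gene = c("g1", "g2"), log2fc = c(2, -1),
                     q = c(0.01, 0.2)),
    SG2 = data.frame(gene = c("g1", "g2"), log2fc = c(-2, -3),
                     q = c(0.001, 0.04))))
  ann <- annotate_module_expression(modules, de)
  expect_identical(ann$SG1, c("+", "=", "="))
  expect_identical(ann$SG2, c("-", "-", "="))
  expect_identical(ann$missing_from_de, c(FALSE, FALSE, TRUE))
})

test_that("planted modules beat degree-preserving nulls in prediction", {
  co <- small_cohort(seed = 12)
  de <- run_diffexpr(co$expr, co$samples)
  uni <- Reduce(union, de$de_sets)
  tum <- co$samples$sample_id[co$samples$group != "control"]
  ne <- expression_matrix(unclass(co$expr)[uni, tum])
  ens <- infer_ensemble(ne, NULL, n_runs = 6, seed = 2)
  cmp <- compare_to_null(ens, ne, NULL, n_null = 2, seed = 3)
  expect_gt(cmp$median_diff, 0)
  expect_lt(cmp$test$p_value, 0.05)
})
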