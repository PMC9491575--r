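# Ensemble lasso gene-regulatory-network inference. The expression of each
# gene is modeled as a linear combination of its own copy number and the
# expression of the other genes of the network universe; predictors enter
# via the lasso path and are tested with the covariance test. Inference is
# repeated over random training subsets; links retained at a q-value cutoff
# (BH within each network) are counted across runs to form a consensus
# network and its modules, and prediction quality on held-out samples is
# compared against degree-preserving null networks.

OWN_CN <- ".own_cn"

#' Fit the lasso model of one gene
#'
#' Response: centered expression of the target over the training samples.
#' Predictors: z-scored own copy number plus z-scored expression of every
#' other gene (training statistics). Predictors entering the lasso path get
#' covariance-test p-values; q-value filtering and the least-squares refit
#' are applied at the ensemble level ([infer_ensemble()]), or here when
#' `q_cutoff` is given.
#'
#' @param target gene id.
#' @param expr expression matrix restricted to the network universe.
#' @param cn gene x sample copy-number matrix (or `NULL` for no CN
#'   covariate).
#' @param train_ids training sample ids (>= 10).
#' @param max_steps maximal path entries per model (default 6).
#' @param sigma2 optional fixed error variance for the covariance test.
#' @param q_cutoff if non-`NULL`, BH-adjust this model's own entry p-values,
#'   keep q <= cutoff, and refit coefficients by least squares.
#' @return a `gene_model` list: target, entries (predictor, order, lambda,
#'   p), sigma2, train_ids, and (after refit) intercept + coefficients.
#' @export
fit_gene_model <- function(target, expr, cn = NULL, train_ids,
                           max_steps = 6L, sigma2 = NULL, q_cutoff = NULL) {
  vals <- unclass(expr)
  if (!target %in% rownames(vals)) stop("target not in expression matrix")
  if (length(train_ids) < 10L) stop("need at least 10 training samples")
  y <- vals[target, train_ids]
  others <- setdiff(rownames(vals), target)
  X <- t(vals[others, train_ids, drop = FALSE])
  if (!is.null(cn) && target %in% rownames(cn)) {
    X <- cbind(cn[target, train_ids], X)
    colnames(X)[1L] <- OWN_CN
  }
  n_tr <- length(train_ids)
  sds <- sqrt(pmax(0, colMeans(X^2) - colMeans(X)^2) * n_tr / (n_tr - 1))
  X <- X[, sds > 1e-12, drop = FALSE]  # constant predictors dropped
  ct <- covariance_test_path(X, y, sigma2 = sigma2, max_steps = max_steps)
  model <- list(target = target, entries = ct,
                sigma2 = attr(ct, "sigma2"), train_ids = train_ids)
  if (!is.null(q_cutoff)) {
    q <- bh_adjust(ct$p)
    model <- refit_gene_model(model, ct$predictor[q <= q_cutoff], expr, cn)
  }
  structure(model, class = "gene_model")
}

# least-squares refit of a gene model on the retained predictor set, on the
# original data scale (so predictions are plain linear combinations)
refit_gene_model <- function(model, retained, expr, cn) {
  vals <- unclass(expr)
  y <- vals[model$target, model$train_ids]
  if (!length(retained)) {
    model$intercept <- mean(y)
    model$coefficients <- numeric(0)
    return(model)
  }
  X <- predictor_matrix(retained, model$target, vals, cn, model$train_ids)
  fit <- lm.fit(cbind(1, X), y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  model$intercept <- cf[1L]
  model$coefficients <- setNames(cf[-1L], retained)
  model
}

predictor_matrix <- function(predictors, target, vals, cn, sample_ids) {
  out <- vapply(predictors, function(pr) {
    if (pr == OWN_CN) cn[target, sample_ids] else vals[pr, sample_ids]
  }, numeric(length(sample_ids)))
  matrix(out, nrow = length(sample_ids),
         dimnames = list(sample_ids, predictors))
}

#' Ensemble network inference over random training subsets
#'
#' Repeats the per-gene lasso modeling `n_runs` times on random training
#' subsets of the configured fraction (default two thirds, e.g. 35 of 53
#' samples); within each run the covariance-test p-values of all entering
#' predictors of all genes form one BH family, links with q at most
#' `link_q` are retained, and retained models are refitted by least
#' squares.
#'
#' @param expr expression matrix restricted to the network universe
#'   (samples with paired copy-number data).
#' @param cn gene x sample copy-number matrix (same samples), or `NULL`.
#' @param n_runs number of resampled networks (default 100).
#' @param train_fraction training fraction (default 2/3; values outside
#'   (0.5, 0.9) trigger a warning).
#' @param link_q per-network link q-value cutoff (default 0.01).
#' @param max_steps maximal path entries per gene model.
#' @param seed master seed; per-run seeds are derived deterministically.
#' @return a `network_ensemble` list: per-run `runs` (train/test ids,
#'   retained `links` data.frame, refitted `models`), plus the settings.
#' @export
infer_ensemble <- function(expr, cn = NULL, n_runs = 100L,
                           train_fraction = 2 / 3, link_q = 0.01,
                           max_steps = 6L, seed = 1L) {
  if (train_fraction <= 0.5 || train_fraction >= 0.9)
    warning("train_fraction outside (0.5, 0.9)")
  vals <- unclass(expr)
  ids <- colnames(vals)
  if (length(ids) < 20L) stop("need at least 20 paired samples")
  if (!is.null(cn) && !all(ids %in% colnames(cn)))
    stop("copy-number matrix lacks expression samples")
  n_train <- round(train_fraction * length(ids))
  genes <- rownames(vals)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed((as.integer(seed) + 7919L * r) %% 2147483647L)
    train <- sort(sample(ids, n_train))
    test <- setdiff(ids, train)
    nt <- length(train)
    # standardized design shared by all targets of this run
    Y <- vals[, train, drop = FALSE]
    Yc <- Y - rowMeans(Y)
    Zc <- t(Yc)
    nrm <- sqrt(colSums(Zc^2))
    ok <- nrm > 1e-12
    Zn <- Zc / rep(pmax(nrm, 1e-12), each = nt)
    colnames(Zn) <- genes
    cnn <- NULL
    if (!is.null(cn)) {
      Cc <- t(cn[genes, train, drop = FALSE])
      Cc <- Cc - rep(colMeans(Cc), each = nt)
      cnrm <- sqrt(colSums(Cc^2))
      cn_ok <- cnrm > 1e-12
      cnn <- Cc / rep(pmax(cnrm, 1e-12), each = nt)
    }
    e_pred <- e_tgt <- vector("list", length(genes))
    e_p <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      sel <- ok
      sel[gi] <- FALSE
      X <- Zn[, sel, drop = FALSE]
      cn_here <- !is.null(cnn) && cn_ok[gi]
      if (cn_here) X <- cbind(cnn[, gi], X, deparse.level = 0)
      nm <- c(if (cn_here) OWN_CN, colnames(Zn)[sel])
      core <- cov_test_core(X, Yc[gi, ], max_steps = max_steps)
      if (length(core$var)) {
        e_pred[[gi]] <- nm[core$var]
        e_tgt[[gi]] <- rep(genes[gi], length(core$var))
        e_p[[gi]] <- core$p
      }
    }
    tab <- NULL
    if (length(unlist(e_p)))
      tab <- data.frame(predictor = unlist(e_pred), target = unlist(e_tgt),
                        p = unlist(e_p), stringsAsFactors = FALSE)
    models <- list()
    links <- NULL
    if (!is.null(tab) && nrow(tab)) {
      tab$q <- bh_adjust(tab$p)
      keep <- tab[tab$q <= link_q, , drop = FALSE]
      for (g in genes) {
        retained <- keep$predictor[keep$target == g]
        mdl <- list(target = g, train_ids = train)
        models[[g]] <- refit_gene_model(mdl, retained, expr, cn)
      }
      if (nrow(keep)) {
        beta <- mapply(function(tg, pr) {
          cf <- models[[tg]]$coefficients
          unname(cf[pr])
        }, keep$target, keep$predictor)
        links <- data.frame(predictor = keep$predictor, target = keep$target,
                            q = keep$q, beta = as.numeric(beta),
                            stringsAsFactors = FALSE)
      }
    }
    runs[[r]] <- list(train = train, test = test, links = links,
                      models = models)
  }
  structure(list(runs = runs, genes = genes, n_runs = n_runs,
                 train_fraction = train_fraction, link_q = link_q,
                 max_steps = max_steps, seed = seed,
                 has_cn = !is.null(cn)),
            class = "network_ensemble")
}

predict_gene <- function(model, target, vals, cn, sample_ids) {
  if (is.null(model$coefficients) || !length(model$coefficients))
    return(NULL)
  X <- predictor_matrix(names(model$coefficients), target, vals, cn,
                        sample_ids)
  drop(model$intercept + X %*% model$coefficients)
}

#' Held-out prediction quality of an ensemble
#'
#' For every network and gene, predicted test-set expression (intercept +
#' coefficients times observed predictor values) is correlated with the
#' measured expression across that network's test samples; per-gene
#' correlations are averaged over networks. Genes whose models never retain
#' a predictor give NA. Networks with fewer than 3 test samples are skipped.
#'
#' @param ensemble a [infer_ensemble()] result.
#' @param expr,cn the matrices used for inference.
#' @return named per-gene mean test-set Pearson correlation.
#' @export
prediction_quality <- function(ensemble, expr, cn = NULL) {
  vals <- unclass(expr)
  acc <- matrix(NA_real_, length(ensemble$genes), length(ensemble$runs),
                dimnames = list(ensemble$genes, NULL))
  for (r in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[r]]
    if (length(run$test) < 3L) { warning("test set of size < 3; run skipped"); next }
    for (g in ensemble$genes) {
      pred <- predict_gene(run$models[[g]], g, vals, cn, run$test)
      if (is.null(pred) || sd(pred) == 0) next
      acc[g, r] <- cor(pred, vals[g, run$test])
    }
  }
  rowMeans(acc, na.rm = TRUE)
}

rewire_links <- function(links, n_swaps_factor = 10L) {
  gg <- links[links$predictor != OWN_CN, , drop = FALSE]
  fixed <- links[links$predictor == OWN_CN, , drop = FALSE]
  m <- nrow(gg)
  if (m >= 2L) {
    key <- function(df) paste(df$predictor, df$target, sep = "\r")
    for (it in seq_len(n_swaps_factor * m)) {
      ij <- sample.int(m, 2L)
      a <- gg[ij[1L], ]; b <- gg[ij[2L], ]
      if (a$predictor == b$target || b$predictor == a$target) next
      new_a <- a; new_b <- b
      new_a$target <- b$target; new_b$target <- a$target
      if (new_a$predictor == new_a$target ||
          new_b$predictor == new_b$target) next
      k <- key(gg)
      if (key(new_a) %in% k || key(new_b) %in% k) next
      gg[ij[1L], ] <- new_a; gg[ij[2L], ] <- new_b
    }
  }
  rbind(gg, fixed)
}

#' Compare ensemble prediction quality to degree-preserving null networks
#'
#' Each learned network is rewired `n_null` times by repeated pair swaps of
#' its gene-gene links, preserving every gene's predictor out-degree and
#' target in-degree (own-copy-number links stay attached to their target);
#' coefficients are refitted by least squares on the training set and
#' evaluated exactly like the real networks. Reports per-gene real and null
#' quality, their paired differences, the median difference, and a paired
#' Wilcoxon signed-rank test.
#'
#' @param ensemble a [infer_ensemble()] result.
#' @param expr,cn the matrices used for inference.
#' @param n_null null networks per learned network (default 10).
#' @param seed seed for the rewiring.
#' @return list: `real`, `null` (per-gene mean correlations), `diff`,
#'   `median_diff`, `test` (signed-rank, one-sided greater).
#' @export
compare_to_null <- function(ensemble, expr, cn = NULL, n_null = 10L,
                            seed = 1L) {
  set.seed(seed)
  vals <- unclass(expr)
  real <- prediction_quality(ensemble, expr, cn)
  acc <- matrix(NA_real_, length(ensemble$genes),
                length(ensemble$runs) * n_null,
                dimnames = list(ensemble$genes, NULL))
  col <- 0L
  for (r in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[r]]
    if (is.null(run$links) || !nrow(run$links) || length(run$test) < 3L) {
      col <- col + n_null; next
    }
    for (b in seq_len(n_null)) {
      col <- col + 1L
      rl <- rewire_links(run$links)
      for (g in unique(rl$target)) {
        mdl <- refit_gene_model(list(target = g, train_ids = run$train),
                                rl$predictor[rl$target == g], expr, cn)
        pred <- predict_gene(mdl, g, vals, cn, run$test)
        if (is.null(pred) || sd(pred) == 0) next
        acc[g, col] <- cor(pred, vals[g, run$test])
      }
    }
  }
  nullq <- rowMeans(acc, na.rm = TRUE)
  ok <- is.finite(real) & is.finite(nullq)
  diff <- real[ok] - nullq[ok]
  list(real = real, null = nullq, diff = diff,
       median_diff = median(diff),
       test = wilcoxon_signed_rank(diff, alternative = "greater"))
}

#' Consensus links and module extraction
#'
#' A directed gene-gene link counts toward support in a run iff it was
#' retained there (q at most the ensemble's link cutoff). Links supported by
#' at least `support_min` runs form the consensus network; its undirected
#' projection is pruned by iteratively removing genes with fewer than
#' `min_links` links within their component until stable, and remaining
#' components of at least `min_module` genes are the modules. Link sign is
#' the majority coefficient sign across supporting runs.
#'
#' @param ensemble a [infer_ensemble()] result (or a data.frame of links
#'   with columns `predictor`, `target`, `support`, for direct use).
#' @param support_min minimal support count (default 75 out of 100 runs,
#'   scaled to `ceiling(0.75 * n_runs)` for other run counts).
#' @param min_links minimal within-module links per gene (default 2).
#' @param min_module minimal module size in genes (default 3).
#' @return list: `links` (consensus data.frame: predictor, target, support,
#'   sign), `modules` (data.frame: module, gene), `graph` (igraph object of
#'   the pruned module graph).
#' @export
consensus_and_modules <- function(ensemble, support_min = NULL,
                                  min_links = 2L, min_module = 3L) {
  if (is.data.frame(ensemble)) {
    sup <- ensemble
    if (is.null(sup$sign)) sup$sign <- 1
    if (is.null(support_min)) stop("support_min required with a link table")
  } else {
    if (is.null(support_min))
      support_min <- ceiling(0.75 * ensemble$n_runs)
    all_links <- do.call(rbind, lapply(ensemble$runs, function(r) r$links))
    if (is.null(all_links) || !nrow(all_links)) {
      return(list(links = data.frame(predictor = character(0),
                                     target = character(0),
                                     support = integer(0), sign = numeric(0)),
                  modules = data.frame(module = integer(0),
                                       gene = character(0)),
                  graph = igraph::make_empty_graph(directed = FALSE)))
    }
    gg <- all_links[all_links$predictor != OWN_CN, , drop = FALSE]
    key <- paste(gg$predictor, gg$target, sep = "\r")
    sup <- aggregate(cbind(support = rep(1L, nrow(gg))),
                     by = list(key = key), FUN = sum)
    sgn <- aggregate(list(sign_sum = sign(gg$beta)),
                     by = list(key = key), FUN = sum)
    sup <- merge(sup, sgn, by = "key")
    parts <- do.call(rbind, strsplit(sup$key, "\r", fixed = TRUE))
    sup <- data.frame(predictor = parts[, 1L], target = parts[, 2L],
                      support = sup$support,
                      sign = ifelse(sup$sign_sum >= 0, 1, -1),
                      stringsAsFactors = FALSE)
  }
  cons <- sup[sup$support >= support_min, , drop = FALSE]
  rownames(cons) <- NULL
  if (!nrow(cons)) {
    return(list(links = cons,
                modules = data.frame(module = integer(0), gene = character(0)),
                graph = igraph::make_empty_graph(directed = FALSE)))
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(
    cons[, c("predictor", "target")], directed = FALSE))
  repeat {
    deg <- igraph::degree(g)
    weak <- names(deg)[deg < min_links]
    if (!length(weak)) break
    g <- igraph::delete_vertices(g, weak)
  }
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_module)
  modules <- data.frame(module = integer(0), gene = character(0))
  if (length(keep_comp)) {
    member <- comp$membership[comp$membership %in% keep_comp]
    relab <- match(member, sort(unique(member)))
    modules <- data.frame(module = relab, gene = names(member),
                          stringsAsFactors = FALSE)
    modules <- modules[order(modules$module, modules$gene), ]
    rownames(modules) <- NULL
  }
  g <- igraph::delete_vertices(
    g, names(comp$membership)[!comp$membership %in% keep_comp])
  list(links = cons, modules = modules, graph = g)
}

#' Per-subgroup expression direction of module genes
#'
#' '+' if the gene is significantly up-regulated (q <= cutoff, positive
#' log2 fold change) in a subgroup versus control, '-' if significantly
#' down, '=' otherwise. Module genes absent from the DE tables are '=' and
#' flagged.
#'
#' @param modules module table from [consensus_and_modules()].
#' @param de differential-expression result ([run_diffexpr()]).
#' @param q_cutoff significance cutoff (default 0.05).
#' @return data.frame: module, gene, one direction column per subgroup,
#'   `missing_from_de` flag.
#' @export
annotate_module_expression <- function(modules, de, q_cutoff = 0.05) {
  sgs <- names(de$tables)
  out <- modules
  out$missing_from_de <- FALSE
  for (sg in sgs) {
    tb <- de$tables[[sg]]
    i <- match(modules$gene, tb$gene)
    dir <- ifelse(is.na(i), "=",
           ifelse(tb$q[i] <= q_cutoff & tb$log2fc[i] > 0, "+",
           ifelse(tb$q[i] <= q_cutoff & tb$log2fc[i] < 0, "-", "=")))
    out[[sg]] <- dir
    out$missing_from_de <- out$missing_from_de | is.na(i)
  }
  out
}
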