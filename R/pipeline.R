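# End-to-end orchestration: simulate (or load) a cohort, then run subgroup
# discovery, differential expression, enrichment, copy-number analysis,
# network inference and survival comparison into a run directory with a
# manifest. A single master seed deterministically derives per-stage seeds
# so stages are independently reproducible.

stage_seed <- function(master, stage) {
  (as.integer(master) %% 97651L) * 13001L +
    sum(utf8ToInt(stage)) * 131L %% 2147483647L
}

#' Pipeline run configuration
#'
#' Defaults follow the analysis settings the package documents throughout:
#' k = 4 subgroups, DE q-cutoff 0.05, CBS alpha 0.01 with 1,000
#' permutations, 100 network runs with support threshold 75 and link
#' q-cutoff 0.01, module rules 2 links / 3 genes.
#'
#' @param ... named overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    k = 4L, de_q = 0.05,
    cbs_alpha = 0.01, cbs_n_perm = 1000L, cbs_min_width = 2L,
    network = TRUE, network_runs = 100L, network_train_fraction = 2 / 3,
    network_support = NULL, network_link_q = 0.01, network_max_steps = 6L,
    network_n_null = 10L,
    au_runs = 10000L, run_au = FALSE, run_stability = FALSE,
    stability_n_remove = 10L, stability_reps = 100L,
    sim = simulation_config(),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        force = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(s)) *
                        (seq_len(nchar(as.character(s))) %% 257)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate, cluster (with optional AU bootstrap and removal
#' stability), differential expression, enrichment (against a catalog built
#' from the planted truth plus random categories), copy-number segmentation
#' and profiles, network inference with consensus modules, and survival
#' comparison. All stage outputs are written as TSV under `out_dir` with a
#' JSON manifest recording the seed, settings hash and package version.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (`NULL` for none: results only returned).
#' @param seed master seed, defaults to `config$seed`.
#' @return invisible list with all stage results.
#' @export
run_all <- function(config = run_config(), out_dir = NULL,
                    seed = config$seed) {
  cfg <- config
  res <- list(config = cfg, seed = seed)

  log_msg("INFO", "simulate")
  cohort <- generate_cohort(cfg$sim, seed = stage_seed(seed, "simulate"))
  res$cohort <- cohort

  log_msg("INFO", "cluster")
  tree <- ward_cluster(correlation_distance(cohort$expr))
  assignment <- cut_tree(tree, cfg$k)
  res$tree <- tree
  res$assignment <- assignment
  if (isTRUE(cfg$run_au))
    res$tree <- au_bootstrap(cohort$expr, n_total_runs = cfg$au_runs,
                             seed = stage_seed(seed, "au"))
  tumor_ids <- cohort$samples$sample_id[cohort$samples$group != "control"]
  if (isTRUE(cfg$run_stability))
    res$stability <- removal_stability(
      cohort$expr, assignment, tumor_ids,
      n_remove = cfg$stability_n_remove, n_reps = cfg$stability_reps,
      seed = stage_seed(seed, "stability"))

  log_msg("INFO", "diffexpr")
  de <- run_diffexpr(cohort$expr, cohort$samples, q_cutoff = cfg$de_q)
  res$de <- de
  res$de_overlaps <- de_overlaps(de)

  log_msg("INFO", "enrichment")
  catalog <- truth_catalog(cohort, seed = stage_seed(seed, "enrich"))
  background <- rownames(cohort$expr)
  res$enrichment <- do.call(rbind, lapply(names(de$de_up), function(sg) {
    rbind(cbind(subgroup = sg,
                enrich(de$de_up[[sg]], "up", catalog, background)),
          cbind(subgroup = sg,
                enrich(de$de_down[[sg]], "down", catalog, background)))
  }))

  log_msg("INFO", "copy number")
  segs <- segment_cbs(cohort$cn_probes, alpha = cfg$cbs_alpha,
                      n_perm = cfg$cbs_n_perm,
                      min_width = cfg$cbs_min_width,
                      seed = stage_seed(seed, "cbs"))
  gene_cn <- map_genes_to_segments(segs, cohort$gene_coords)
  cn_groups <- setNames(cohort$samples$group, cohort$samples$sample_id)
  res$segments <- segs
  res$gene_cn <- gene_cn
  res$cn_profiles <- subgroup_median_profile(
    gene_cn, cn_groups[colnames(gene_cn)])

  if (isTRUE(cfg$network)) {
    log_msg("INFO", "network")
    universe <- Reduce(union, de$de_sets)
    cn_samples <- colnames(gene_cn)
    net_expr <- expression_matrix(unclass(cohort$expr)[universe, cn_samples])
    ens <- infer_ensemble(net_expr, gene_cn[universe, , drop = FALSE],
                          n_runs = cfg$network_runs,
                          train_fraction = cfg$network_train_fraction,
                          link_q = cfg$network_link_q,
                          max_steps = cfg$network_max_steps,
                          seed = stage_seed(seed, "network"))
    res$ensemble <- ens
    res$consensus <- consensus_and_modules(ens,
                                           support_min = cfg$network_support)
    res$quality <- compare_to_null(ens, net_expr,
                                   gene_cn[universe, , drop = FALSE],
                                   n_null = cfg$network_n_null,
                                   seed = stage_seed(seed, "null"))
    res$module_annotation <-
      annotate_module_expression(res$consensus$modules, de, cfg$de_q)
  }

  log_msg("INFO", "survival")
  tum <- cohort$samples[cohort$samples$group != "control" &
                          !is.na(cohort$samples$time_days), ]
  res$survival <- list(
    km_by_group = lapply(split(tum, tum$group), function(d)
      km_estimate(d$time_days, d$status)),
    logrank_group = logrank_test(tum$time_days, tum$status, tum$group),
    logrank_sex = logrank_test(tum$time_days, tum$status, tum$sex))

  if (!is.null(out_dir)) write_run(res, out_dir)
  invisible(res)
}

# annotation catalog derived from the planted truth: one category per
# planted block plus random categories as a null background
truth_catalog <- function(cohort, n_random = 20L, size_random = 40L,
                          seed = 1L) {
  set.seed(seed)
  genes <- rownames(cohort$expr)
  tr <- cohort$truth
  sets <- list(SHARED_TUMOR_PROGRAM = tr$shared_block,
               SG23_PROGRAM = tr$close_block)
  for (sg in colnames(tr$de_shift)) {
    only <- tr$de_status[, sg] & rowSums(tr$de_status) == 1
    sets[[paste0(sg, "_PROGRAM")]] <- rownames(tr$de_shift)[only]
  }
  for (i in seq_len(n_random))
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(genes, size_random)
  structure(sets, family = setNames(rep("synthetic", length(sets)),
                                    names(sets)))
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(res$cohort, file.path(out_dir, "cohort"))
  write.table(data.frame(sample_id = names(res$assignment),
                         cluster = as.integer(res$assignment)),
              file.path(out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (sg in names(res$de$tables))
    write.table(res$de$tables[[sg]],
                file.path(out_dir, paste0("de_", sg, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$enrichment, file.path(out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$segments, file.path(out_dir, "segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$consensus)) {
    write.table(res$consensus$links, file.path(out_dir, "consensus_links.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$consensus$modules, file.path(out_dir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package = "tpllsubtyper",
    version = as.character(packageVersion("tpllsubtyper")),
    seed = res$seed,
    config_hash = config_hash(res$config),
    stages = names(res))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
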