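# Synthetic cohort generator. Emulates the statistical structure the
# analysis pipeline assumes: three tumor subgroups plus a normal control
# group, a hierarchy in which SG2 and SG3 are mutually closer than SG1,
# shared and subgroup-specific differentially expressed genes, segmental
# copy-number alterations partially coupled to cis expression, a sparse
# planted hub-regulator network, and exponential survival with censoring.
# Everything is reproducible from (config, seed) and the planted truth is
# returned alongside the data.

#' Default synthetic-cohort configuration
#'
#' Group sizes mirror a cohort of 10 controls and 18/11/39 tumor samples in
#' three subgroups; the gene count defaults to 2,000 for desk-scale speed.
#' Expression is Gaussian on log2 scale (microarray-like). The hierarchy
#' ((SG2, SG3), SG1) is induced by an extra shift block (`delta_close`)
#' shared by SG2 and SG3 only. Copy-number segments are specified per
#' chromosome with per-subgroup penetrance, and carrier expression of
#' in-segment genes is shifted by `kappa` per unit of copy-number log-ratio.
#'
#' @param ... named overrides of any default field.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    n_control = 10L, n_sg1 = 18L, n_sg2 = 11L, n_sg3 = 39L,
    base_mean = 8, base_mean_sd = 1.5,       # per-gene baseline, log2 units
    noise_sd_range = c(0.5, 1.0),            # per-gene residual sd
    frac_de_shared = 0.15,                   # DE in all three subgroups
    frac_de_subgroup = 0.05,                 # DE specific to each subgroup
    frac_close = 0.05,                       # extra SG2/SG3-shared block
    shared_shift = 1.8, subgroup_shift = 1.5,
    delta_close = 1.2,                       # log2 shift of the close block
    prob_down = 0.6,                         # more down- than up-regulation
    # genome: chromosomes chr1..chr10, 100 Mb each; genes laid out evenly
    n_chromosomes = 10L, chrom_length = 1e8,
    probes_per_chrom = 120L, cn_noise_sd = 0.15,
    cn_segments = list(
      list(chrom = "chr8", start = 1,    end = 4e7,  log_ratio = -0.5,
           subgroups = c("SG1", "SG2", "SG3"), penetrance = 0.85),
      list(chrom = "chr8", start = 6e7,  end = 1e8,  log_ratio = 0.45,
           subgroups = c("SG1", "SG3"), penetrance = 0.85),
      list(chrom = "chr6", start = 5e7,  end = 9e7,  log_ratio = -0.4,
           subgroups = c("SG2", "SG3"), penetrance = 0.6),
      list(chrom = "chr9", start = 1e7,  end = 5e7,  log_ratio = 0.4,
           subgroups = "SG1", penetrance = 0.7)),
    kappa = 0.7,                             # cis expression per CN log-ratio
    network = list(on = TRUE, n_hubs = 8L, targets_per_hub = 2L,
                   weight_range = c(1.2, 1.6), noise_sd = 0.2),
    survival = list(baseline_hazard = 1 / 600,  # per day
                    sex_hazard_ratio = 2,       # female vs male
                    censoring_hazard = 1 / 1500),
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_de_shared, cfg$frac_de_subgroup, cfg$frac_close, cfg$prob_down)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (any(unlist(cfg[c("n_control", "n_sg1", "n_sg2", "n_sg3")]) < 2))
    stop("all group sizes must be >= 2")
  if ((cfg$shared_shift != 0 || cfg$subgroup_shift != 0) &&
      cfg$frac_de_shared == 0 && cfg$frac_de_subgroup == 0)
    stop("nonzero effect sizes requested with zero DE genes")
  for (seg in cfg$cn_segments) {
    if (seg$end > cfg$chrom_length || seg$start < 1)
      stop("copy-number segment outside declared chromosome length")
    if (seg$penetrance < 0 || seg$penetrance > 1)
      stop("penetrance must lie in [0, 1]")
  }
  by_chr <- split(cfg$cn_segments,
                  vapply(cfg$cn_segments, `[[`, "", "chrom"))
  for (segs in by_chr) {
    if (length(segs) < 2) next
    iv <- t(vapply(segs, function(s) c(s$start, s$end), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping copy-number segments on one chromosome")
  }
  if (cfg$survival$baseline_hazard <= 0) stop("baseline hazard must be > 0")
  structure(cfg, class = "sim_config")
}

sim_group_labels <- function(cfg) {
  c(rep("control", cfg$n_control), rep("SG1", cfg$n_sg1),
    rep("SG2", cfg$n_sg2), rep("SG3", cfg$n_sg3))
}

#' Generate a full synthetic cohort with planted ground truth
#'
#' Expression = per-gene baseline + group shifts + hub-network propagation +
#' cis copy-number coupling + Gaussian noise. Returns the expression matrix,
#' a sample metadata table (including simulated sex, age, pretreatment and
#' survival) and the complete planted truth (labels, per-gene per-subgroup
#' shifts, copy-number carriers and segments, network edges).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return list with elements `expr`, `samples`, `truth`, `cn_probes`,
#'   `gene_coords`.
#' @export
generate_cohort <- function(config = simulation_config(), seed = config$seed) {
  cfg <- validate_sim_config(config)
  set.seed(seed)
  labels <- sim_group_labels(cfg)
  n <- length(labels)
  ids <- sprintf("%s%02d", ifelse(labels == "control", "NC", "TP"), seq_len(n))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # ---- planted differential-expression structure
  ng <- cfg$n_genes
  n_shared <- round(cfg$frac_de_shared * ng)
  n_close  <- round(cfg$frac_close * ng)
  n_sg     <- round(cfg$frac_de_subgroup * ng)
  pool <- sample.int(ng)  # random gene order; blocks are disjoint
  take <- function(k) { out <- pool[seq_len(k)]; pool <<- pool[-seq_len(k)]; out }
  idx_shared <- take(n_shared)
  idx_close  <- take(n_close)
  idx_sg <- list(SG1 = take(n_sg), SG2 = take(n_sg), SG3 = take(n_sg))

  sgn <- function(k) ifelse(runif(k) < cfg$prob_down, -1, 1)
  shift <- matrix(0, ng, 3, dimnames = list(genes, c("SG1", "SG2", "SG3")))
  shift[idx_shared, ] <- cfg$shared_shift * sgn(n_shared)      # same in all
  shift[idx_close, c("SG2", "SG3")] <-
    shift[idx_close, c("SG2", "SG3")] + cfg$delta_close * sgn(n_close)
  for (g in names(idx_sg))
    shift[idx_sg[[g]], g] <- shift[idx_sg[[g]], g] + cfg$subgroup_shift * sgn(n_sg)

  # ---- planted hub network layout (genes chosen before noise is drawn)
  hubs <- tmat <- NULL
  if (isTRUE(cfg$network$on) && cfg$network$n_hubs > 0) {
    if (cfg$network$n_hubs %% 2L != 0L)
      stop("network n_hubs must be even (hubs act in co-regulating pairs)")
    n_pairs <- cfg$network$n_hubs %/% 2L
    net_pool <- idx_shared
    need <- cfg$network$n_hubs + n_pairs * 2L * cfg$network$targets_per_hub
    if (length(net_pool) < need)
      stop("not enough shared DE genes to host the planted network")
    picked <- sample(net_pool, need)
    hubs <- matrix(picked[seq_len(cfg$network$n_hubs)], nrow = 2L)
    tmat <- matrix(picked[-seq_len(cfg$network$n_hubs)], ncol = n_pairs)
  }

  # ---- baseline + group means + noise
  base <- rnorm(ng, cfg$base_mean, cfg$base_mean_sd)
  noise_sd <- runif(ng, cfg$noise_sd_range[1], cfg$noise_sd_range[2])
  # module genes are tightly co-regulated: their residual noise around the
  # shared latent program is small, while the genes keep their planted
  # group shifts (they remain detectably differential)
  if (!is.null(hubs))
    noise_sd[c(as.vector(hubs), as.vector(tmat))] <- cfg$network$noise_sd
  mu <- matrix(base, ng, n)
  for (g in c("SG1", "SG2", "SG3"))
    mu[, labels == g] <- mu[, labels == g] + shift[, g]
  values <- mu + matrix(rnorm(ng * n), ng, n) * noise_sd
  dimnames(values) <- list(genes, ids)

  # ---- planted co-regulation modules: each module is driven by two latent
  # regulator activities (patient-level, independent of the group shifts);
  # the two "hub" genes track one activity each (with a small admixture of
  # the other) and every shared target mixes both. All module genes are
  # tightly coupled to the latent program, so their mutual dependencies are
  # strong and mutually complementary - the structure the consensus-module
  # machinery is designed to detect.
  edges <- NULL
  if (!is.null(hubs)) {
    n_pairs <- ncol(hubs)
    rho <- 25 * pi / 180  # angular radius of the loading ring
    edges <- vector("list", n_pairs)
    for (pp in seq_len(n_pairs)) {
      tg <- tmat[, pp]
      m <- 2L + length(tg)
      # module loading directions sit on a ring of angular radius rho
      # around a shared direction in a 3-dimensional latent activity space:
      # every gene then has two flanking neighbors whose contributions are
      # complementary, so each gene's two strongest partners are its ring
      # neighbors and the consensus graph closes into a cycle
      f <- matrix(rnorm(3L * n), 3L, n)  # latent activities per sample
      half <- m %/% 2L
      ring_idx <- integer(m)             # hubs opposite each other
      ring_idx[1L] <- hubs[1L, pp]
      ring_idx[1L + half] <- hubs[2L, pp]
      ring_idx[ring_idx == 0L] <- tg
      phi <- 2 * pi * (seq_len(m) - 1L) / m
      loadings <- cbind(cos(rho),
                        sin(rho) * cos(phi),
                        sin(rho) * sin(phi))
      # module-wide coupling scale on log2 units (uniform within a module
      # so that no ring edge is systematically weaker than the rest)
      sf <- rep(0.5 * runif(1L, cfg$network$weight_range[1],
                            cfg$network$weight_range[2]), m)
      values[ring_idx, ] <- values[ring_idx, ] + (sf * loadings) %*% f
      nxt <- c(seq(2L, m), 1L)
      edges[[pp]] <- data.frame(hub = genes[ring_idx],
                                target = genes[ring_idx[nxt]],
                                weight = (sf + sf[nxt]) / 2)
    }
    edges <- do.call(rbind, edges)
  }

  # ---- gene coordinates and copy number (cis-coupled)
  gene_coords <- sim_gene_coords(cfg, genes)
  cn <- generate_copy_number(cfg, labels = labels, sample_ids = ids,
                             gene_coords = gene_coords)
  values <- values + cfg$kappa * cn$gene_effect  # zero outside carriers

  # ---- metadata and survival
  sex <- sample(c("male", "female"), n, replace = TRUE)
  surv <- generate_survival(cfg, labels = labels, sexes = sex)
  samples <- sample_table(data.frame(
    sample_id = ids, group = labels, sex = sex,
    age_years = round(runif(n, 40, 85)),
    pretreated = labels != "control" & runif(n) < 0.2,
    stage = ifelse(labels == "control", NA, "active"),
    tcl1a_status = ifelse(labels == "control", NA,
                          sample(c("positive", "weak", "negative"), n,
                                 replace = TRUE, prob = c(0.8, 0.1, 0.1))),
    time_days = surv$time_days, status = surv$status,
    stringsAsFactors = FALSE))

  truth <- list(
    seed = seed, labels = setNames(labels, ids),
    de_shift = shift, de_status = shift != 0,
    close_block = genes[idx_close], shared_block = genes[idx_shared],
    network_edges = edges,
    cn_segments = cfg$cn_segments, cn_carriers = cn$carriers,
    gene_cn = cn$gene_cn)
  list(expr = expression_matrix(values), samples = samples, truth = truth,
       cn_probes = cn$probes, gene_coords = gene_coords)
}

sim_gene_coords <- function(cfg, genes) {
  ng <- length(genes)
  chrom <- paste0("chr", rep_len(seq_len(cfg$n_chromosomes), ng))
  per <- ave(seq_len(ng), chrom, FUN = seq_along)
  n_per <- ave(seq_len(ng), chrom, FUN = length)
  start <- floor(cfg$chrom_length * (per - 0.5) / n_per)
  data.frame(gene_id = genes, chrom = chrom,
             start = start, end = start + 2e4,  # 20 kb genes
             stringsAsFactors = FALSE)
}

#' Generate probe-level copy-number data for a cohort
#'
#' For every configured segment, tumor samples of the affected subgroups are
#' carriers with the configured penetrance; carrier probes inside the segment
#' read `log_ratio` + noise, all other probes 0 + noise. The per-gene true
#' copy-number matrix (`gene_cn`) and the cis expression offset
#' (`gene_effect`, the carrier log-ratio per in-segment gene, to be scaled by
#' `kappa`) are returned alongside the probe table.
#'
#' @param cfg a [simulation_config()].
#' @param labels group label per sample.
#' @param sample_ids sample identifiers.
#' @param gene_coords gene coordinate table (gene_id, chrom, start, end).
#' @return list with `probes` (sample_id, chrom, pos, log2ratio),
#'   `gene_cn`, `gene_effect`, `carriers`.
#' @export
generate_copy_number <- function(cfg, labels, sample_ids, gene_coords) {
  n <- length(sample_ids)
  probe_pos <- floor(seq(1, cfg$chrom_length,
                         length.out = cfg$probes_per_chrom))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  grid <- expand.grid(pos = probe_pos, chrom = chroms,
                      stringsAsFactors = FALSE)[, c("chrom", "pos")]
  ng <- nrow(gene_coords)
  true_probe <- matrix(0, nrow(grid), n)      # noiseless probe signal
  gene_cn <- matrix(0, ng, n,
                    dimnames = list(gene_coords$gene_id, sample_ids))
  carriers <- list()
  tumor <- labels != "control"
  mid <- floor((gene_coords$start + gene_coords$end) / 2)
  for (k in seq_along(cfg$cn_segments)) {
    seg <- cfg$cn_segments[[k]]
    elig <- which(labels %in% seg$subgroups)
    carr <- elig[runif(length(elig)) < seg$penetrance]
    carriers[[k]] <- sample_ids[carr]
    pidx <- which(grid$chrom == seg$chrom &
                    grid$pos >= seg$start & grid$pos <= seg$end)
    gidx <- which(gene_coords$chrom == seg$chrom &
                    mid >= seg$start & mid <= seg$end)
    true_probe[pidx, carr] <- true_probe[pidx, carr] + seg$log_ratio
    gene_cn[gidx, carr] <- gene_cn[gidx, carr] + seg$log_ratio
  }
  noisy <- true_probe
  noisy[, tumor] <- noisy[, tumor] +
    matrix(rnorm(nrow(grid) * sum(tumor), 0, cfg$cn_noise_sd),
           nrow(grid), sum(tumor))
  probes <- data.frame(
    sample_id = rep(sample_ids[tumor], each = nrow(grid)),
    chrom = rep(grid$chrom, sum(tumor)),
    pos = rep(grid$pos, sum(tumor)),
    log2ratio = as.vector(noisy[, tumor]),
    stringsAsFactors = FALSE)
  list(probes = probes, gene_cn = gene_cn[, tumor, drop = FALSE],
       gene_effect = gene_cn, carriers = carriers)
}

#' Generate exponential survival times with sex-specific hazard
#'
#' Event times are exponential with hazard `baseline_hazard`, multiplied by
#' `sex_hazard_ratio` for females; censoring times are independent
#' exponential with hazard `censoring_hazard`. Controls receive no survival
#' information (NA).
#'
#' @param cfg a [simulation_config()].
#' @param labels group label per sample.
#' @param sexes `"male"`/`"female"` per sample.
#' @return data.frame with `time_days` and `status` (`died` / `censored`).
#' @export
generate_survival <- function(cfg, labels, sexes) {
  n <- length(labels)
  hz <- cfg$survival$baseline_hazard *
    ifelse(sexes == "female", cfg$survival$sex_hazard_ratio, 1)
  ev <- rexp(n, hz)
  cs <- if (cfg$survival$censoring_hazard > 0)
    rexp(n, cfg$survival$censoring_hazard) else rep(Inf, n)
  time <- pmin(ev, cs)
  status <- ifelse(ev <= cs, "died", "censored")
  tumor <- labels != "control"
  data.frame(time_days = ifelse(tumor, round(time, 1), NA),
             status = ifelse(tumor, status, NA),
             stringsAsFactors = FALSE)
}

#' Write a generated cohort to a directory in the package's on-disk formats
#'
#' Emits `expression.tsv`, `samples.tsv`, `cn_probes.tsv`,
#' `gene_coords.tsv` and `truth.yaml` (planted-truth summary with the seed
#' recorded).
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expr, file.path(dir, "expression.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write.table(cohort$cn_probes, file.path(dir, "cn_probes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$gene_coords, file.path(dir, "gene_coords.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  yaml::write_yaml(list(
    seed = tr$seed,
    labels = as.list(tr$labels),
    de_genes_per_subgroup = lapply(colnames(tr$de_shift), function(g)
      rownames(tr$de_shift)[tr$de_status[, g]]),
    network_edges = if (is.null(tr$network_edges)) list() else
      split(tr$network_edges[c("target", "weight")], tr$network_edges$hub)),
    file.path(dir, "truth.yaml"))
  invisible(dir)
}
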