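test_that("cohort generation is fully reproducible from (config, seed)", {
  a <- generate_cohort(small_sim_config(), seed = 5)
  b <- generate_cohort(small_sim_config(), seed = 5)
  expect_identical(unclass(a$expr), unclass(b$expr))
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$de_shift, b$truth$de_shift)
  c <- generate_cohort(small_sim_config(), seed = 6)
  expect_false(identical(unclass(a$expr), unclass(c$expr)))
})

test_that("null configuration yields no group differences beyond chance", {
  cfg <- small_sim_config(shared_shift = 0, subgroup_shift = 0,
                          delta_close = 0, frac_de_shared = 0,
                          frac_de_subgroup = 0, frac_close = 0,
                          kappa = 0, network = list(on = FALSE, n_hubs = 0L,
                                                    targets_per_hub = 0L,
                                                    weight_range = c(1, 1),
                                                    noise_sd = 0.2))
  co <- generate_cohort(cfg, seed = 9)
  v <- unclass(co$expr)
  grp <- co$samples$group
  p <- apply(v, 1, function(r)
    t.test(r[grp == "SG1"], r[grp == "control"])$p.value)
  rej <- mean(p <= 0.05)
  expect_lt(abs(rej - 0.05), 0.035)
})

test_that("planted differential genes show the configured shift", {
  co <- small_cohort(seed = 3)
  cfg <- small_sim_config()
  v <- unclass(co$expr)
  grp <- co$samples$group
  tr <- co$truth
  # shared-only genes not in the network and not CN-coupled
  net_genes <- unique(c(tr$network_edges$hub, tr$network_edges$target))
  cn_genes <- rownames(tr$gene_cn)[rowSums(tr$gene_cn != 0) > 0]
  pure <- setdiff(setdiff(tr$shared_block, net_genes), cn_genes)
  sh <- tr$de_shift[pure, "SG1"]
  obs <- rowMeans(v[pure, grp == "SG1", drop = FALSE]) -
    rowMeans(v[pure, grp == "control", drop = FALSE])
  bound <- 3 * max(cfg$noise_sd_range) * sqrt(1 / 8 + 1 / 6)
  expect_true(all(abs(obs - sh) < bound))
})

test_that("copy-number generation respects penetrance and coupling", {
  # penetrance 1, zero noise: carrier probes read the configured log-ratio exactly
  cfg <- small_sim_config(cn_noise_sd = 0,
                          cn_segments = list(list(chrom = "chr2", start = 1,
                                                  end = 5e7, log_ratio = 0.7,
                                                  subgroups = c("SG1", "SG2", "SG3"),
                                                  penetrance = 1)))
  co <- generate_cohort(cfg, seed = 4)
  pr <- co$cn_probes
  inseg <- pr$chrom == "chr2" & pr$pos <= 5e7
  expect_true(all(pr$log2ratio[inseg] == 0.7))
  expect_true(all(pr$log2ratio[!inseg] == 0))

  # kappa = 0 decouples expression from copy number
  cfg0 <- small_sim_config(kappa = 0)
  co0 <- generate_cohort(cfg0, seed = 4)
  carr <- rownames(co0$truth$gene_cn)[rowSums(co0$truth$gene_cn != 0) > 0]
  tum <- colnames(co0$truth$gene_cn)
  cors <- vapply(carr[1:50], function(g) {
    cn <- co0$truth$gene_cn[g, tum]
    if (sd(cn) == 0) return(0)
    cor(unclass(co0$expr)[g, tum], cn)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("subgroup-restricted duplication leaves other subgroups flat", {
  cfg <- small_sim_config(cn_segments = list(
    list(chrom = "chr8", start = 6e7, end = 1e8, log_ratio = 0.5,
         subgroups = c("SG1", "SG3"), penetrance = 1)))
  co <- generate_cohort(cfg, seed = 8)
  tum <- co$samples$sample_id[co$samples$group != "control"]
  grp <- setNames(co$samples$group, co$samples$sample_id)[tum]
  gcn <- co$truth$gene_cn
  arm <- co$gene_coords$gene_id[co$gene_coords$chrom == "chr8" &
                                  co$gene_coords$start >= 6e7]
  med <- subgroup_median_profile(gcn[arm, tum], grp)
  expect_true(all(med[, "SG2"] == 0))
  expect_true(all(med[, "SG1"] == 0.5))
})

test_that("overlapping segment specs and bad fractions are rejected", {
  expect_error(small_sim_config(cn_segments = list(
    list(chrom = "chr1", start = 1, end = 5e7, log_ratio = 0.5,
         subgroups = "SG1", penetrance = 1),
    list(chrom = "chr1", start = 4e7, end = 9e7, log_ratio = -0.5,
         subgroups = "SG2", penetrance = 1))), "overlap")
  expect_error(small_sim_config(frac_de_shared = 1.2), "\\[0, 1\\]")
  expect_error(small_sim_config(frac_de_shared = 0, frac_de_subgroup = 0),
               "zero DE genes")
})

test_that("survival generation follows its hazard specification", {
  cfg <- small_sim_config()
  labels <- rep("SG1", 400)
  sexes <- rep(c("male", "female"), each = 200)

  # no censoring branch
  cfg$survival$censoring_hazard <- 0
  set.seed(1)
  s0 <- generate_survival(cfg, labels, sexes)
  expect_true(all(s0$status == "died"))

  # hazard ratio 1: sex-balanced medians within Monte-Carlo error
  cfg$survival$sex_hazard_ratio <- 1
  set.seed(2)
  s1 <- generate_survival(cfg, labels, sexes)
  m <- median(s1$time_days[sexes == "male"])
  f <- median(s1$time_days[sexes == "female"])
  expect_lt(abs(log(m / f)), 0.5)
})

test_that("log-rank power against hazard ratio 2 matches design", {
  cfg <- small_sim_config()
  cfg$survival$sex_hazard_ratio <- 2
  labels <- rep("SG1", 1000)
  sexes <- rep(c("male", "female"), each = 500)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    sv <- generate_survival(cfg, labels, sexes)
    logrank_test(sv$time_days, sv$status, sexes)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
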