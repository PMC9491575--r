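probe_frame <- function(x, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq_along(x), log2ratio = x)
}

test_that("zero-noise two-level signals split exactly at the step", {
  x <- c(rep(0, 60), rep(1, 60))
  segs <- segment_cbs(probe_frame(x), n_perm = 300, seed = 1)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$end_idx[1], 60L)
  expect_equal(segs$mean, c(0, 1))
  expect_equal(sum(segs$n_probes), 120)
})

test_that("a 6-sigma step is located within 2 probes", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- c(rnorm(100), rnorm(100, 6))
    segs <- segment_cbs(probe_frame(x), alpha = 0.01, n_perm = 300,
                        seed = s + 1000)
    any(abs(segs$end_idx - 100) <= 2)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure noise rarely splits and constants never do", {
  splits <- vapply(1:60, function(s) {
    set.seed(s)
    segs <- segment_cbs(probe_frame(rnorm(150)), alpha = 0.01,
                        n_perm = 300, seed = s + 5000)
    nrow(segs) > 1
  }, logical(1))
  expect_lte(mean(splits), 0.01 + 2 * sqrt(0.01 * 0.99 / 60))

  segs0 <- segment_cbs(probe_frame(rep(0.3, 80)), n_perm = 200, seed = 1)
  expect_identical(nrow(segs0), 1L)
  expect_equal(segs0$mean, 0.3)
})

test_that("segmentation is invariant to adding a constant", {
  set.seed(3)
  x <- c(rnorm(80), rnorm(60, 4))
  s1 <- segment_cbs(probe_frame(x), n_perm = 400, seed = 7)
  s2 <- segment_cbs(probe_frame(x + 5), n_perm = 400, seed = 7)
  expect_identical(s1$end_idx, s2$end_idx)
  expect_equal(s2$mean, s1$mean + 5, tolerance = 1e-12)
})

test_that("segment means reconstruct the fitted signal with lower RSS", {
  set.seed(5)
  x <- c(rnorm(70), rnorm(70, 3))
  segs <- segment_cbs(probe_frame(x), n_perm = 400, seed = 2)
  fitted <- rep(segs$mean, segs$n_probes)
  expect_lte(sum((x - fitted)^2), sum((x - mean(x))^2))
})

test_that("input validation catches malformed probe series", {
  bad <- data.frame(chrom = "chr1", pos = c(3, 2, 5), log2ratio = 0)
  expect_error(segment_cbs(bad), "increasing")
  expect_warning(segment_cbs(probe_frame(rnorm(50)), n_perm = 50, seed = 1),
                 "coarse")
})

test_that("gene-segment mapping follows the midpoint and tie rules", {
  segs <- data.frame(sample_id = "S1", chrom = "chr1",
                     start_idx = c(1L, 51L), end_idx = c(50L, 100L),
                     start_bp = c(100L, 5100L), end_bp = c(5000L, 10000L),
                     n_probes = c(50L, 50L), mean = c(0.8, -0.4))
  gc <- data.frame(gene_id = c("inside", "boundary", "nochrom"),
                   chrom = c("chr1", "chr1", "chr9"),
                   start = c(2000L, 5050L, 100L),
                   end = c(2400L, 5150L, 200L))
  out <- map_genes_to_segments(segs, gc)
  expect_equal(out["inside", "S1"], 0.8)
  # midpoint 5100 falls exactly on the second segment's start: left rule
  expect_equal(out["boundary", "S1"], 0.8)
  expect_true(is.na(out["nochrom", "S1"]))
  expect_error(map_genes_to_segments(segs,
                                     data.frame(gene_id = "b", chrom = "chr1",
                                                start = 10, end = 5)),
               "start > end")
})

test_that("gene mapping equals a brute-force interval oracle", {
  set.seed(11)
  x <- c(rnorm(60), rnorm(60, 5), rnorm(60, -3))
  probes <- data.frame(chrom = "chr1", pos = sort(sample(1:5000, 180)),
                       log2ratio = x)
  segs <- segment_cbs(probes, n_perm = 400, seed = 3)
  gc <- data.frame(gene_id = paste0("g", 1:50), chrom = "chr1",
                   start = sample(1:4900, 50))
  gc$end <- gc$start + 50
  out <- map_genes_to_segments(segs, gc)
  bnd <- segs$start_bp[-1]
  for (i in seq_len(nrow(gc))) {
    mid <- floor((gc$start[i] + gc$end[i]) / 2)
    k <- sum(mid > bnd) + 1  # count-based oracle; ties go left
    expect_equal(out[gc$gene_id[i], "S1"], segs$mean[k])
  }
})

test_that("median profiles and recurrent calls match direct computation", {
  m <- rbind(g1 = c(-1, 0, 1, 0.5), g2 = c(NA, NA, 0.3, 0.4))
  colnames(m) <- paste0("s", 1:4)
  asg <- setNames(c("A", "A", "A", "B"), colnames(m))
  med <- subgroup_median_profile(m, asg)
  expect_equal(med["g1", "A"], 0)
  expect_equal(med["g1", "B"], 0.5)
  expect_equal(med["g2", "A"], 0.3)  # NA-dropping median
  expect_equal(med["g2", "B"], 0.4)

  freq <- recurrent_alterations(m, asg, call_threshold = 0.4)
  expect_equal(freq$deletion["g1", "A"], 1 / 3)
  expect_equal(freq$duplication["g1", "A"], 1 / 3)
  expect_equal(freq$duplication["g1", "B"], 1)
  expect_error(recurrent_alterations(m, asg, call_threshold = 0), "> 0")

  set.seed(2)
  mm <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  aa <- setNames(rep(c("X", "Y"), each = 5), colnames(mm))
  fr <- recurrent_alterations(mm, aa, 0.3)
  expect_equal(fr$deletion[, "X"], rowMeans(mm[, 1:5] <= -0.3))
  expect_equal(fr$duplication[, "Y"], rowMeans(mm[, 6:10] >= 0.3))
})
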