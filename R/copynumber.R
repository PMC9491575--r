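# Copy-number analysis: circular binary segmentation (CBS) of probe
# log2-ratios with a permutation split criterion, gene-level assignment of
# segment means, per-subgroup median profiles and recurrent-alteration
# frequencies.

segment_one <- function(x, pos, alpha, n_perm, min_width) {
  n <- length(x)
  emit <- function(from, to) data.frame(
    start_idx = from, end_idx = to, start_bp = pos[from], end_bp = pos[to],
    n_probes = to - from + 1L, mean = mean(x[from:to]))
  rec <- function(from, to) {
    len <- to - from + 1L
    if (len < 2L * min_width) return(emit(from, to))
    seg <- x[from:to]
    sc <- cbs_scan(seg, min_width)
    if (sc[1] <= 0) return(emit(from, to))
    exceed <- cbs_perm_count(seg, min_width, n_perm, sc[1])
    p <- (1 + exceed) / (n_perm + 1)
    if (p > alpha) return(emit(from, to))
    i <- as.integer(sc[2]); j <- as.integer(sc[3])  # arc is seg[(i+1)..j]
    cuts <- unique(c(0L, i, j, len))
    pieces <- lapply(seq_len(length(cuts) - 1L), function(q)
      rec(from + cuts[q], from + cuts[q + 1L] - 1L))
    do.call(rbind, pieces)
  }
  rec(1L, n)
}

#' Circular binary segmentation of copy-number probe log-ratios
#'
#' Recursively splits each chromosome's probe series at the arc that
#' maximizes the two-sample t-like statistic over all arc pairs; a split is
#' accepted when its permutation p-value (random reshuffles of the
#' within-segment probe order) is at most `alpha`, and the recursion
#' continues on the resulting pieces. Segment means are emitted per piece.
#' Segmentation is invariant to adding a constant to all probes.
#'
#' @param probes data.frame with columns `chrom`, `pos` (bp, 1-based,
#'   strictly increasing within chromosome), `log2ratio`, and optionally
#'   `sample_id` (default single sample `"S1"`).
#' @param alpha split acceptance level (default 0.01).
#' @param n_perm permutations per tested split (default 1,000; values below
#'   100 trigger a warning).
#' @param min_width minimal number of probes per segment (default 2).
#' @param seed integer seed for the permutation reshuffles.
#' @return data.frame of segments: sample_id, chrom, start_bp, end_bp,
#'   start_idx, end_idx (probe indices within chromosome), n_probes, mean.
#' @export
segment_cbs <- function(probes, alpha = 0.01, n_perm = 1000L, min_width = 2L,
                        seed = 1L) {
  if (n_perm < 100L) warning("n_perm < 100 gives a coarse permutation p-value")
  if (is.null(probes$sample_id)) probes$sample_id <- "S1"
  set.seed(seed)
  out <- list()
  for (sid in unique(probes$sample_id)) {
    ps <- probes[probes$sample_id == sid, , drop = FALSE]
    for (ch in unique(ps$chrom)) {
      pc <- ps[ps$chrom == ch, , drop = FALSE]
      if (is.unsorted(pc$pos, strictly = TRUE))
        stop("probe positions not strictly increasing: sample ", sid,
             ", chromosome ", ch)
      if (nrow(pc) < min_width)
        stop("fewer than min_width probes on ", ch, " for sample ", sid)
      segs <- segment_one(pc$log2ratio, pc$pos, alpha, n_perm, min_width)
      segs <- data.frame(sample_id = sid, chrom = ch, segs,
                         stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- segs
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Map genes to copy-number segments
#'
#' Each gene receives the mean log2-ratio of the segment containing its
#' midpoint. Within a chromosome the segments partition the whole axis: the
#' boundary between consecutive segments is the later segment's first probe
#' position, and a midpoint falling exactly on that boundary is assigned to
#' the left (lower-coordinate) segment. Genes on chromosomes without probes
#' get NA.
#'
#' @param segments segment table from [segment_cbs()].
#' @param gene_coords data.frame: gene_id, chrom, start, end (1-based
#'   inclusive).
#' @return gene x sample matrix of assigned log2-ratios.
#' @export
map_genes_to_segments <- function(segments, gene_coords) {
  if (any(gene_coords$start > gene_coords$end))
    stop("malformed gene coordinates: start > end")
  mid <- floor((gene_coords$start + gene_coords$end) / 2)
  samples <- unique(segments$sample_id)
  out <- matrix(NA_real_, nrow(gene_coords), length(samples),
                dimnames = list(gene_coords$gene_id, samples))
  for (sid in samples) {
    ss <- segments[segments$sample_id == sid, , drop = FALSE]
    for (ch in unique(ss$chrom)) {
      sc <- ss[ss$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$start_bp), , drop = FALSE]
      g <- which(gene_coords$chrom == ch)
      if (!length(g)) next
      bnd <- sc$start_bp[-1L]
      idx <- findInterval(mid[g], bnd, left.open = TRUE) + 1L
      out[g, sid] <- sc$mean[idx]
    }
  }
  out
}

#' Per-subgroup median copy-number profiles
#'
#' @param gene_cn gene x sample matrix of log2-ratios (NA allowed).
#' @param assignment named vector of subgroup labels per sample.
#' @return gene x subgroup matrix of medians (NA when a subgroup has no
#'   non-missing value for a gene).
#' @export
subgroup_median_profile <- function(gene_cn, assignment) {
  assignment <- assignment[colnames(gene_cn)]
  if (anyNA(assignment)) stop("samples missing from assignment")
  groups <- sort(unique(as.character(assignment)))
  vapply(groups, function(g) {
    cols <- gene_cn[, assignment == g, drop = FALSE]
    apply(cols, 1, function(r)
      if (all(is.na(r))) NA_real_ else median(r, na.rm = TRUE))
  }, numeric(nrow(gene_cn)))
}

#' Recurrent deletion / duplication frequencies per subgroup
#'
#' A gene is called deleted in a sample when its log2-ratio is at most
#' `-call_threshold` and duplicated when at least `+call_threshold`.
#'
#' @param gene_cn gene x sample log2-ratio matrix.
#' @param assignment named subgroup labels per sample.
#' @param call_threshold positive calling threshold (default 0.2).
#' @return list of gene x subgroup matrices `deletion` and `duplication`
#'   with per-subgroup call frequencies.
#' @export
recurrent_alterations <- function(gene_cn, assignment, call_threshold = 0.2) {
  if (call_threshold <= 0) stop("call_threshold must be > 0")
  assignment <- assignment[colnames(gene_cn)]
  groups <- sort(unique(as.character(assignment)))
  freq <- function(cmp) vapply(groups, function(g) {
    cols <- gene_cn[, assignment == g, drop = FALSE]
    rowMeans(cmp(cols), na.rm = TRUE)
  }, numeric(nrow(gene_cn)))
  list(deletion = freq(function(m) m <= -call_threshold),
       duplication = freq(function(m) m >= call_threshold))
}
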