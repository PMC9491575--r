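# Cross-cohort subgroup transfer: parametric empirical-Bayes batch
# adjustment of the joint (reference + incoming) matrix followed by
# nearest-positive-correlation label assignment.

#' Batch-adjust a reference and an incoming expression cohort
#'
#' Genes are intersected first, the two cohorts form the two batches, and
#' the parametric empirical-Bayes location/scale adjustment (normal prior
#' on additive batch effects, inverse-gamma on multiplicative ones,
#' moment-estimated hyperpriors) is applied via `sva::ComBat` with standard
#' settings. A single-batch input is returned unchanged (identity).
#'
#' @param reference expression matrix of the labeled cohort.
#' @param incoming expression matrix of the new cohort (or `NULL` to treat
#'   `reference` as a single batch).
#' @param min_genes minimal gene overlap required (default 500).
#' @return list: `adjusted` (joint genes x samples matrix), `batch`
#'   (factor), `reference_ids`, `incoming_ids`.
#' @export
combat_adjust <- function(reference, incoming = NULL, min_genes = 500L) {
  ref <- unclass(reference)
  if (is.null(incoming)) {
    return(list(adjusted = ref,
                batch = factor(rep("reference", ncol(ref))),
                reference_ids = colnames(ref), incoming_ids = character(0)))
  }
  inc <- unclass(incoming)
  genes <- intersect(rownames(ref), rownames(inc))
  if (!length(genes)) stop("reference and incoming cohorts share no genes")
  if (length(genes) < min_genes)
    stop("gene overlap below the required minimum of ", min_genes)
  if (ncol(ref) < 2L || ncol(inc) < 2L)
    stop("each batch needs at least 2 samples")
  joint <- cbind(ref[genes, , drop = FALSE], inc[genes, , drop = FALSE])
  batch <- factor(c(rep("reference", ncol(ref)), rep("incoming", ncol(inc))),
                  levels = c("reference", "incoming"))
  # genes constant within the joint matrix break the standardization; keep
  # them unadjusted
  keep <- apply(joint, 1, sd) > 1e-12
  adjusted <- joint
  if (any(keep)) {
    adjusted[keep, ] <- suppressMessages(
      sva::ComBat(dat = joint[keep, , drop = FALSE], batch = batch))
  }
  list(adjusted = adjusted, batch = batch,
       reference_ids = colnames(ref), incoming_ids = colnames(inc))
}

#' Transfer subgroup labels by strongest positive correlation
#'
#' Each incoming sample is correlated (Pearson, over the shared gene space)
#' with every reference sample and assigned the subgroup label of the
#' reference sample with the strongest positive correlation (ties broken by
#' reference id order). Samples whose best correlation is not positive are
#' reported as unassignable rather than raising an error; assignments with
#' best correlation below `confidence_floor` are flagged low-confidence.
#'
#' @param adjusted joint adjusted matrix from [combat_adjust()] (or any
#'   genes x samples matrix containing both cohorts).
#' @param ref_labels named vector of subgroup labels for the reference
#'   samples.
#' @param incoming_ids ids of the samples to classify.
#' @param confidence_floor low-confidence threshold on the best correlation
#'   (default 0.2).
#' @return data.frame: sample_id, label, best_match, r, low_confidence.
#' @export
transfer_labels <- function(adjusted, ref_labels, incoming_ids,
                            confidence_floor = 0.2) {
  ref_ids <- names(ref_labels)
  stopifnot(all(ref_ids %in% colnames(adjusted)),
            all(incoming_ids %in% colnames(adjusted)))
  r <- cor(adjusted[, incoming_ids, drop = FALSE],
           adjusted[, ref_ids, drop = FALSE])
  out <- lapply(seq_along(incoming_ids), function(i) {
    ri <- r[i, ]
    best <- which.max(ri)  # first maximum = lowest reference id order
    if (ri[best] <= 0) {
      return(data.frame(sample_id = incoming_ids[i], label = "unassignable",
                        best_match = NA_character_, r = ri[best],
                        low_confidence = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(sample_id = incoming_ids[i],
               label = as.character(ref_labels[ref_ids[best]]),
               best_match = ref_ids[best], r = unname(ri[best]),
               low_confidence = ri[best] < confidence_floor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare subgroup count distributions of two cohorts
#'
#' Exact Fisher test on the 2 x k table of cohort by subgroup counts.
#'
#' @param counts_a,counts_b named integer vectors over the same labels.
#' @return a `tpll_test` result.
#' @export
compare_distributions <- function(counts_a, counts_b) {
  if (!identical(sort(names(counts_a)), sort(names(counts_b))))
    stop("count vectors must cover the same labels")
  tab <- rbind(counts_a, counts_b[names(counts_a)])
  fisher_exact_rxc(tab)
}
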