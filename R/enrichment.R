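# Direction-stratified category enrichment: one-sided Fisher's exact test
# of differentially expressed genes against annotation categories, with BH
# correction within a category family per direction.

#' Gene-set over-representation test for one DE set
#'
#' Each category is intersected with the background (all measured genes)
#' and tested with the 2 x 2 one-sided Fisher's exact test
#' \[in-category & DE, in-category & not DE; out & DE, out & not DE\].
#' Categories with no background overlap are reported with p = 1. q-values
#' are BH-adjusted across the categories of the same family (all categories
#' if no family tags are present).
#'
#' @param de_set character vector of DE gene ids (subset of `background`).
#' @param direction label stored in the result (`"up"`, `"down"`, ...).
#' @param catalog named list of category gene sets (see
#'   [read_annotation_sets()]); an optional `family` attribute groups
#'   categories into separate multiple-testing families.
#' @param background character vector of all measured gene ids.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return data.frame: category, family, direction, count, category_size,
#'   de_size, background_size, odds_ratio, p, q.
#' @export
enrich <- function(de_set, direction, catalog, background,
                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  background <- unique(background)
  if (!length(background)) stop("background gene set is empty")
  de_set <- unique(de_set)
  if (!all(de_set %in% background))
    stop("de_set must be a subset of the background")
  fams <- attr(catalog, "family")
  if (is.null(fams)) fams <- setNames(rep(NA_character_, length(catalog)),
                                      names(catalog))
  N <- length(background); n_de <- length(de_set)
  rows <- lapply(names(catalog), function(cat) {
    members <- intersect(catalog[[cat]], background)
    K <- length(members)
    k <- length(intersect(members, de_set))
    if (K == 0) {
      p <- 1; or <- NA_real_
    } else {
      tab <- matrix(c(k, n_de - k, K - k, N - K - (n_de - k)), 2, 2)
      p <- fisher_exact_rxc(tab, alternative = alternative)$p_value
      or <- (k * (N - K - n_de + k)) / max(1e-12, (K - k) * (n_de - k))
      if ((K - k) == 0 || (n_de - k) == 0) or <- Inf
      if (k == 0) or <- 0
    }
    data.frame(category = cat, family = unname(fams[cat]),
               direction = direction, count = k, category_size = K,
               de_size = n_de, background_size = N,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  fam_key <- ifelse(is.na(res$family), "", res$family)
  res$q <- NA_real_
  for (f in unique(fam_key)) {
    i <- fam_key == f
    res$q[i] <- bh_adjust(res$p[i])
  }
  res[order(res$p), ]
}

#' Per-category Venn overlap of subgroup-specific altered genes
#'
#' For every annotation category, the seven disjoint Venn region counts of
#' the three subgroups' DE members within that category.
#'
#' @param de_sets named list of three DE gene-id vectors (one per subgroup).
#' @param catalog named list of category gene sets.
#' @return data.frame with one row per category and the region counts of
#'   [venn3()].
#' @export
pathway_overlap_report <- function(de_sets, catalog) {
  stopifnot(length(de_sets) == 3L)
  out <- lapply(names(catalog), function(cat) {
    members <- catalog[[cat]]
    v <- venn3(lapply(de_sets, intersect, y = members))
    data.frame(category = cat, t(v), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
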