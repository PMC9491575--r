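# Hierarchical subgroup discovery: 1 - Pearson correlation distance between
# sample profiles, Ward (ward.D2) agglomeration, k-cluster cuts, multiscale
# bootstrap support (approximately unbiased p-values) and patient-removal
# stability.

#' Correlation distance between sample expression profiles
#'
#' d(i, j) = 1 - r(i, j) with r the Pearson correlation of the two samples'
#' gene profiles; values lie in \[0, 2\]. Invariant to per-sample affine
#' transforms with positive scale.
#'
#' @param x expression matrix (genes x samples).
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
correlation_distance <- function(x) {
  v <- apply(unclass(x), 2, var)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  d <- 1 - cor(unclass(x))
  diag(d) <- 0
  d
}

#' Ward (ward.D2) hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the ward.D2 update (Lance-Williams
#' recurrence on squared distances applied to unsquared input, as the
#' criterion defines). Deterministic given the input order.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return an object of class `hclust`.
#' @export
ward_cluster <- function(d) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!all(is.finite(d))) stop("non-finite distance value(s)")
    d <- as.dist(d)
  } else if (!all(is.finite(d))) stop("non-finite distance value(s)")
  hclust(d, method = "ward.D2")
}

#' Cut a dendrogram into k subgroups
#'
#' Removes the k - 1 highest merges. Cluster labels are renumbered by
#' dendrogram left-to-right order so that naming is reproducible; partitions
#' are nested as k increases.
#'
#' @param tree an `hclust` object.
#' @param k number of clusters (1..n leaves).
#' @return named integer vector of cluster labels in 1..k, with attribute
#'   `k`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  raw <- cutree(tree, k = k)
  first_pos <- vapply(seq_len(k), function(cl)
    min(match(names(raw)[raw == cl], tree$labels[tree$order])), numeric(1))
  # renumber: cluster appearing leftmost in the dendrogram becomes 1, etc.
  new_id <- integer(k)
  new_id[order(first_pos)] <- seq_len(k)
  out <- setNames(new_id[raw], names(raw))
  attr(out, "k") <- as.integer(k)
  out
}

# canonical string key of an internal node's leaf set
node_keys <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- unlist(lapply(tree$merge[i, ], function(j)
      if (j < 0) tree$labels[-j] else members[[j]]))
    members[[i]] <- m
  }
  vapply(members, function(m) paste(sort(m), collapse = "\r"), character(1))
}

#' Multiscale bootstrap support for a sample dendrogram
#'
#' Repeats the clustering on gene resamples of several sizes
#' (`ceiling(tau * n_genes)` genes drawn with replacement for each scale
#' `tau`), records per-node bootstrap frequencies, and extrapolates to the
#' approximately unbiased (AU) p-value by the probit fit
#' `qnorm(1 - BP_tau) = v * sqrt(tau) + c / sqrt(tau)` (weighted least
#' squares, binomial weights). `AU = 1 - pnorm(v - c)` and the fitted
#' bootstrap probability is `1 - pnorm(v + c)`. Frequencies of exactly 0 or
#' 1 are clamped to (eps, 1 - eps) with eps = 1 / (2 * replicates) before
#' the probit transform; nodes never observed in any replicate get AU = 0.
#'
#' @param x expression matrix (genes x samples).
#' @param n_total_runs total bootstrap replicates across all scales
#'   (default 10,000).
#' @param scales resampling scale factors tau; must span values below and
#'   above 1.
#' @param seed integer seed.
#' @return the `hclust` tree of the full data with a data.frame attribute
#'   `support` (one row per internal node: `au`, `bp_fit`, `bp_raw`, `v`,
#'   `c`).
#' @export
au_bootstrap <- function(x, n_total_runs = 10000L,
                         scales = seq(0.5, 1.4, by = 0.1), seed = 1L) {
  if (length(scales) < 2L || min(scales) >= 1 || max(scales) <= 1)
    stop("scales must include values below and above 1")
  set.seed(seed)
  vals <- unclass(x)
  ng <- nrow(vals)
  tree <- ward_cluster(correlation_distance(x))
  keys <- node_keys(tree)
  reps <- max(1L, round(n_total_runs / length(scales)))
  counts <- matrix(0, length(keys), length(scales),
                   dimnames = list(NULL, paste0("tau", scales)))
  for (s in seq_along(scales)) {
    m <- as.integer(ceiling(scales[s] * ng))
    for (r in seq_len(reps)) {
      idx <- sample.int(ng, m, replace = TRUE)
      sub <- vals[idx, , drop = FALSE]
      v <- apply(sub, 2, var)
      if (any(v == 0)) next  # degenerate resample; skip
      bt <- hclust(as.dist(1 - cor(sub)), method = "ward.D2")
      counts[, s] <- counts[, s] + (keys %in% node_keys(bt))
    }
  }
  bp <- counts / reps
  eps <- 1 / (2 * reps)
  support <- t(vapply(seq_along(keys), function(i) {
    if (all(counts[i, ] == 0)) return(c(au = 0, bp_fit = 0,
                                        bp_raw = bp[i, length(scales)], v = NA, c = NA))
    # recovered in every replicate at every scale: AU = 1 within clamping
    # precision (the probit fit is degenerate for a constant frequency)
    if (all(counts[i, ] == reps)) return(c(au = 1, bp_fit = 1, bp_raw = 1,
                                           v = NA, c = NA))
    b <- pmin(pmax(bp[i, ], eps), 1 - eps)
    z <- qnorm(1 - b)
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    w <- reps * dnorm(z)^2 / (b * (1 - b))   # binomial delta-method weights
    fit <- lm.wfit(X, z, w)
    vc <- fit$coefficients
    c(au = 1 - pnorm(vc[1] - vc[2]), bp_fit = 1 - pnorm(vc[1] + vc[2]),
      bp_raw = unname(bp[i, which.min(abs(scales - 1))]),
      v = unname(vc[1]), c = unname(vc[2]))
  }, numeric(5)))
  attr(tree, "support") <- as.data.frame(support)
  attr(tree, "scales") <- scales
  attr(tree, "replicates_per_scale") <- reps
  tree
}

# pair clusters of a new partition to reference clusters greedily by
# descending overlap; ties broken by larger reference-cluster size, then by
# label order
pair_clusters <- function(new_labels, ref_labels) {
  kn <- sort(unique(new_labels)); kr <- sort(unique(ref_labels))
  ov <- table(factor(new_labels, kn), factor(ref_labels, kr))
  ref_size <- table(factor(ref_labels, kr))
  used_n <- used_r <- character(0)
  cand <- expand.grid(n = rownames(ov), r = colnames(ov),
                      stringsAsFactors = FALSE)
  cand$overlap <- mapply(function(a, b) ov[a, b], cand$n, cand$r)
  cand$rsize <- as.vector(ref_size[cand$r])
  cand <- cand[order(-cand$overlap, -cand$rsize, cand$r, cand$n), ]
  map <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$n[i] %in% used_n || cand$r[i] %in% used_r) next
    map[cand$n[i]] <- cand$r[i]
    used_n <- c(used_n, cand$n[i]); used_r <- c(used_r, cand$r[i])
  }
  map
}

#' Stability of subgroup assignments under random patient removal
#'
#' Repeatedly removes `n_remove` tumor samples at random, re-runs the
#' clustering (1 - Pearson distance, ward.D2) on the remaining samples, cuts
#' at the reference k, pairs the new clusters to the reference clusters by
#' majority overlap (greedy, each cluster used once) and scores the fraction
#' of retained samples whose paired label matches the reference assignment.
#'
#' @param x expression matrix (genes x samples).
#' @param reference reference assignment from [cut_tree()] (named vector).
#' @param tumor_ids sample ids eligible for removal (tumor samples).
#' @param n_remove number of samples removed per replicate (0..10 typical).
#' @param n_reps number of replicates.
#' @param seed integer seed.
#' @return list with `correctness` (per-replicate fractions) and `median`.
#' @export
removal_stability <- function(x, reference, tumor_ids, n_remove = 10L,
                              n_reps = 100L, seed = 1L) {
  if (n_remove < 0) stop("n_remove must be >= 0")
  k <- attr(reference, "k")
  if (is.null(k)) k <- length(unique(reference))
  set.seed(seed)
  ids <- colnames(x)
  stopifnot(all(tumor_ids %in% ids), all(names(reference) %in% ids))
  correctness <- vapply(seq_len(n_reps), function(r) {
    drop <- if (n_remove > 0) sample(tumor_ids, n_remove) else character(0)
    keep <- setdiff(ids, drop)
    sub <- x[, keep, drop = FALSE]
    new <- cut_tree(ward_cluster(correlation_distance(sub)), k)
    map <- pair_clusters(as.character(new), as.character(reference[keep]))
    mean(map[as.character(new)] == as.character(reference[keep]))
  }, numeric(1))
  list(correctness = correctness, median = median(correctness))
}
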