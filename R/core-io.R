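#' @useDynLib tpllsubtyper, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import stats
#' @importFrom utils read.delim write.table head packageVersion
"_PACKAGE"

# ---- ExpressionMatrix ----------------------------------------------------

#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 expression values
#' with genes in rows and samples in columns; row and column names carry the
#' gene and sample identifiers. Validation enforces unique identifiers,
#' finite values and a minimal 2 x 2 extent.
#'
#' @param values numeric matrix, genes x samples, log2 scale.
#' @param gene_ids,sample_ids optional character vectors overriding dimnames.
#' @return the validated matrix (invisibly classed `"expr_matrix"`).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("expression matrix needs gene and sample identifiers")
  rownames(values) <- as.character(gene_ids)
  colnames(values) <- as.character(sample_ids)
  validate_expression_matrix(values)
  class(values) <- c("expr_matrix", class(values))
  values
}

validate_expression_matrix <- function(values) {
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("expression matrix must have at least 2 genes and 2 samples")
  dup_g <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(dup_g, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  invisible(values)
}

#' Read a genes-x-samples expression matrix from TSV
#'
#' The canonical interchange format is a tab-separated table whose header row
#' holds sample identifiers and whose first column holds gene identifiers.
#' Values are assumed to be already normalized, on log2 scale; the package
#' never re-normalizes.
#'
#' @param path file path to a TSV file.
#' @param orientation `"genes"` (default) if rows are genes, `"samples"` if
#'   the table is transposed on disk.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("malformed expression table (need id column plus >=1 data column): ", path)
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1L)))
    stop("non-numeric expression value(s) in column(s): ",
         paste(colnames(tab)[-1L][bad], collapse = ", "))
  }
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix to TSV
#'
#' @param x expression matrix.
#' @param path output path.
#' @param digits number of significant decimal digits retained (default 6).
#' @return the path, invisibly.
#' @export
write_expression_matrix <- function(x, path, digits = 6L) {
  df <- data.frame(gene_id = rownames(x), round(unclass(x), digits),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- SampleTable ---------------------------------------------------------

sample_table_cols <- c("sample_id", "group", "sex", "age_years", "pretreated",
                       "stage", "tcl1a_status", "time_days", "status")

#' Construct / validate a sample metadata table
#'
#' Fixed columns: `sample_id`, `group` (control / subgroup label / unknown),
#' `sex`, `age_years`, `pretreated`, `stage`, `tcl1a_status`, `time_days`
#' (survival time from diagnosis, days), `status` (`"died"` for events,
#' `"censored"` for non-informative censoring, `NA` if missing). Missing
#' metadata other than `sample_id` is tolerated (NA); missing columns are
#' added as NA.
#'
#' @param df data.frame with at least `sample_id` and `group`.
#' @return validated data.frame.
#' @export
sample_table <- function(df) {
  if (!"sample_id" %in% names(df)) stop("sample table lacks sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyNA(df$sample_id) || any(df$sample_id == ""))
    stop("sample_id must not be missing")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (cc in setdiff(sample_table_cols, names(df))) df[[cc]] <- NA
  st <- !is.na(df$status)
  if (!all(df$status[st] %in% c("died", "censored")))
    stop("status must be 'died', 'censored' or NA")
  tt <- !is.na(df$time_days)
  if (any(df$time_days[tt] < 0)) stop("time_days must be >= 0")
  df[, sample_table_cols]
}

#' Read a sample metadata table from TSV
#' @param path TSV path with the fixed column names of [sample_table()].
#' @return validated data.frame.
#' @export
read_sample_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  sample_table(df)
}

#' Write a sample metadata table to TSV
#' @param df sample table.
#' @param path output path.
#' @export
write_sample_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- AnnotationCatalog (GMT) --------------------------------------------

#' Read gene-set annotations from a GMT file
#'
#' Standard GMT: one category per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are deduplicated. An optional `family` argument tags every category
#' with an annotation family (signaling / metabolic / gene-class), used
#' downstream to form separate multiple-testing families.
#'
#' @param path GMT file path.
#' @param family optional single family tag for all categories in the file.
#' @return a named list of character vectors with attribute `family`
#'   (named character vector, one entry per category).
#' @export
read_annotation_sets <- function(path, family = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  fams <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    sets[[parts[[1L]]]] <- unique(parts[-(1:2)])
    fams[parts[[1L]]] <- family
  }
  structure(sets, family = fams)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_annotation_sets <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# ---- Probe collapsing ----------------------------------------------------

#' Collapse a probe-level matrix to gene level
#'
#' Technical replicate columns of the same patient are averaged first, then
#' probe rows mapping to the same gene are averaged, mirroring how raw
#' microarray tables are reduced to one profile per patient and one row per
#' gene. The result is invariant to probe/row order.
#'
#' @param probe_matrix numeric matrix, probes x samples.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (many-to-one).
#' @param replicate_map optional data.frame with columns `sample_id`,
#'   `patient_id`; samples missing from it keep their own id.
#' @return an [expression_matrix()] with one row per distinct gene.
#' @export
collapse_probes <- function(probe_matrix, probe_map, replicate_map = NULL) {
  probe_matrix <- as.matrix(probe_matrix)
  if (anyDuplicated(probe_map$probe_id))
    stop("probe_map maps a probe to more than one gene")
  missing <- setdiff(rownames(probe_matrix), probe_map$probe_id)
  if (length(missing))
    stop("probe(s) absent from map: ", paste(missing, collapse = ", "))
  # replicate columns first
  ids <- colnames(probe_matrix)
  patient <- ids
  if (!is.null(replicate_map)) {
    idx <- match(ids, replicate_map$sample_id)
    patient[!is.na(idx)] <- as.character(replicate_map$patient_id[idx[!is.na(idx)]])
  }
  col_groups <- split(seq_along(ids), factor(patient, levels = unique(patient)))
  m <- vapply(col_groups, function(j)
    rowMeans(probe_matrix[, j, drop = FALSE]), numeric(nrow(probe_matrix)))
  # then probe rows per gene
  gene <- probe_map$gene_id[match(rownames(probe_matrix), probe_map$probe_id)]
  gsum <- rowsum(m, group = gene, reorder = TRUE)
  gcnt <- as.vector(table(gene)[rownames(gsum)])
  expression_matrix(gsum / gcnt)
}

# ---- Logging -------------------------------------------------------------

log_msg <- function(level = "INFO", ..., verbose = getOption("tpllsubtyper.verbose", FALSE)) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}
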