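# Readers, writers and identifier reconciliation for the tabular inputs:
# expression matrices (genes x samples), clinical tables, subtype centroid
# tables and gene lists. All files are TSV, UTF-8. Identifier matching is
# exact-string and case-sensitive throughout: silent case-folding creates
# irreproducible gene overlaps.

DAYS_PER_MONTH <- 365.25 / 12

#' Validate an expression matrix
#'
#' An expression matrix is a numeric matrix of log2 expression values with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames; all values must be finite (the pipeline has no imputation step,
#' so missing values are rejected).
#'
#' @param x numeric matrix, genes x samples.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression must be a numeric matrix (genes x samples)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopf("expression matrix must carry gene rownames and sample colnames")
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g))
    stopf("duplicate gene ids: %s", paste(utils::head(dup_g, 5), collapse = ", "))
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stopf("duplicate sample ids: %s", paste(utils::head(dup_s, 5), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    stopf("expression matrix contains missing or non-finite values")
  invisible(x)
}

#' Validate a clinical table
#'
#' A clinical table is a data.frame with columns `sample_id` (unique strings),
#' `arm` (0 = control, 1 = experimental), `pfs_months` (positive PFS time in
#' months) and `event` (1 = progression observed, 0 = censored).
#'
#' @param clin data.frame as above.
#' @return `clin`, invisibly, after validation.
#' @export
validate_clinical <- function(clin) {
  need <- c("sample_id", "arm", "pfs_months", "event")
  miss <- setdiff(need, names(clin))
  if (length(miss)) stopf("clinical table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(clin$sample_id)) stopf("duplicate sample ids in clinical table")
  if (!all(clin$arm %in% c(0, 1))) stopf("arm must be 0 (control) or 1 (experimental)")
  if (!all(is.finite(clin$pfs_months)) || any(clin$pfs_months <= 0))
    stopf("pfs_months must be positive and finite")
  if (!all(clin$event %in% c(0, 1))) stopf("event must be 0 (censored) or 1 (event)")
  invisible(clin)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column, as in the genes-x-samples supplementary matrices the method
#' consumes.
#'
#' @param path path to a tab-separated text file.
#' @return numeric matrix, genes x samples, with identifier dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("expression file needs a gene-id column plus >= 1 sample")
  gene_ids <- as.character(df[[1]])
  sample_ids <- names(df)[-1]   # before data.frame subsetting repairs duplicates
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(suppress) & !is.na(v))
      if (length(bad))
        stopf("non-numeric expression value at row %d, column '%s'",
              bad[1], names(vals)[j])
      vals[[j]] <- suppress
    }
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(gene_ids, sample_ids)
  validate_expression(x)
  msg("read_expression: %d genes x %d samples from %s", nrow(x), ncol(x), path)
  x
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]; round trips are bit-exact (values are
#' written with full precision).
#'
#' @param x expression matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  validate_expression(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical metadata table from TSV
#'
#' @param path path to a tab-separated file.
#' @param columns named character vector mapping the canonical column names
#'   (`sample_id`, `arm`, `pfs_months`, `event`) to the column names actually
#'   present in the file; identity by default.
#' @param time_unit `"months"` (default) or `"days"`; days are converted with
#'   one month = 365.25/12 days.
#' @return data.frame with columns sample_id, arm, pfs_months, event.
#' @export
read_clinical <- function(path, columns = NULL, time_unit = c("months", "days")) {
  time_unit <- match.arg(time_unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  map <- c(sample_id = "sample_id", arm = "arm",
           pfs_months = "pfs_months", event = "event")
  if (!is.null(columns)) map[names(columns)] <- columns
  miss <- map[!map %in% names(df)]
  if (length(miss))
    stopf("clinical file lacks columns: %s", paste(miss, collapse = ", "))
  clin <- data.frame(sample_id = as.character(df[[map["sample_id"]]]),
                     arm = as.numeric(df[[map["arm"]]]),
                     pfs_months = as.numeric(df[[map["pfs_months"]]]),
                     event = as.numeric(df[[map["event"]]]),
                     stringsAsFactors = FALSE)
  if (time_unit == "days") clin$pfs_months <- clin$pfs_months / DAYS_PER_MONTH
  validate_clinical(clin)
  clin
}

#' Write a clinical table to TSV
#' @param clin clinical table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  validate_clinical(clin)
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subtype centroid table from TSV
#'
#' Format: gene identifiers in the first column, one column per centroid
#' (e.g. the six LP colorectal subtype centroids on 57 genes, or the four
#' CMS consensus centroids).
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, genes x centroids.
#' @export
read_centroids <- function(path) {
  x <- read_expression(path)
  validate_centroids(x)
  x
}

#' Validate a centroid set
#' @param x numeric matrix, genes x centroids.
#' @return `x`, invisibly.
#' @export
validate_centroids <- function(x) {
  validate_expression(x)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stopf("constant centroid column(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  invisible(x)
}

#' Read a gene list (one identifier per line)
#' @param path path to a text file; lines beginning with '#' are skipped.
#' @param name optional name for the set.
#' @return character vector of unique gene ids with a `name` attribute.
#' @export
read_geneset <- function(path, name = basename(path)) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (!length(ids)) stopf("gene list '%s' is empty", path)
  if (anyDuplicated(ids)) stopf("duplicate ids in gene list '%s'", path)
  structure(ids, name = name)
}

#' Restrict expression and clinical data to their common samples
#'
#' Both outputs are restricted to the (non-empty) intersection of sample ids
#' and put in the same sample order.
#'
#' @param expr expression matrix.
#' @param clin clinical table.
#' @return list with elements `expr` and `clin`.
#' @export
align_samples <- function(expr, clin) {
  validate_expression(expr)
  validate_clinical(clin)
  common <- intersect(colnames(expr), clin$sample_id)
  if (!length(common)) stopf("no samples in common between expression and clinical data")
  dropped <- (ncol(expr) - length(common)) + (nrow(clin) - length(common))
  msg("align_samples: %d common samples, %d ids dropped", length(common), dropped)
  clin2 <- clin[match(common, clin$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr[, common, drop = FALSE], clin = clin2)
}

#' Restrict an expression matrix to a set of genes
#'
#' Rows are restricted to the overlap with `other_ids`, ordered as in
#' `other_ids` (only genes overlapping between the two components are used,
#' e.g. a centroid table's genes against the profiled genes).
#'
#' @param expr expression matrix.
#' @param other_ids character vector of gene ids.
#' @return expression matrix restricted to the overlap.
#' @export
intersect_genes <- function(expr, other_ids) {
  validate_expression(expr)
  keep <- other_ids[other_ids %in% rownames(expr)]
  if (!length(keep)) stopf("no genes in common")
  msg("intersect_genes: %d of %d requested genes present", length(keep), length(other_ids))
  expr[keep, , drop = FALSE]
}
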