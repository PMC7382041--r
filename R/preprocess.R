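# Quantile normalization and per-gene standardization of the expression
# matrix. Standardization maps each gene row x to (x - mean)/sd with the
# sample (n-1) standard deviation; quantile normalization forces every
# sample column onto the cross-column mean of order statistics.

#' Quantile-normalize an expression matrix
#'
#' After normalization every column holds the same multiset of values (the
#' cross-column mean of order statistics), assigned within each column in the
#' column's original rank order. Ties share the average of the reference
#' values across the tied ranks.
#'
#' @param expr expression matrix (genes x samples), >= 2 samples.
#' @return expression matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2) stopf("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Standardize each gene to mean 0 and unit sample standard deviation
#'
#' Genes with zero sample variance cannot be standardized; they are dropped
#' with a warning and recorded in the returned parameters.
#'
#' @param expr expression matrix.
#' @return list with `expr` (standardized matrix, zero-variance genes removed)
#'   and `params`, a `standardization_params` object holding per-gene means and
#'   sds (and the ids of excluded genes) for later out-of-sample application.
#' @export
standardize <- function(expr) {
  validate_expression(expr)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  drop <- sdv == 0
  if (all(drop)) stopf("all genes have zero variance; nothing to standardize")
  if (any(drop))
    warnf("dropping %d zero-variance gene(s): %s", sum(drop),
          paste(utils::head(rownames(expr)[drop], 5), collapse = ", "))
  keep <- !drop
  y <- (expr[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  params <- structure(
    list(gene_ids = rownames(expr)[keep], means = unname(mu[keep]),
         sds = unname(sdv[keep]), excluded = rownames(expr)[drop]),
    class = "standardization_params")
  list(expr = y, params = params)
}

#' Apply previously fitted standardization parameters
#'
#' Uses the stored training means/sds rather than recomputing them, so test
#' samples can be standardized without information leakage.
#'
#' @param expr expression matrix whose genes are all covered by `params`.
#' @param params a `standardization_params` object from [standardize()].
#' @return standardized matrix with the same dimnames as `expr`.
#' @export
apply_standardization <- function(expr, params) {
  validate_expression(expr)
  stopifnot(inherits(params, "standardization_params"))
  idx <- match(rownames(expr), params$gene_ids)
  if (anyNA(idx))
    stopf("gene(s) absent from standardization params: %s",
          paste(utils::head(rownames(expr)[is.na(idx)], 5), collapse = ", "))
  (expr - params$means[idx]) / params$sds[idx]
}

#' @export
print.standardization_params <- function(x, ...) {
  cat(sprintf("standardization params: %d genes (%d excluded as zero-variance)\n",
              length(x$gene_ids), length(x$excluded)))
  invisible(x)
}
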