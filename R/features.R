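# Dimensional reduction: the three strategies producing the K reduced
# covariates of the interaction Cox model.
#
#  * subC — correlation of each sample's profile with molecular-subtype
#    centroids, Fisher-transformed (zeta = atanh(r)) and mean-centered.
#  * MOA  — a-priori mechanism-of-action gene list, per-gene interaction-p
#    ranking, top-mtop selection, then (by default) the first principal
#    component of the selected genes as a single covariate.
#  * SPC  — supervised principal components: the same interaction-p selection
#    applied genome-wide, followed by the top-K principal components.
#
# All fitting (ranking, PC bases, centering means) consumes training samples
# only; projection onto held-out samples reuses the stored training state.

CLIP_R <- 1 - 1e-6  # |r| clip before atanh, which diverges at |r| = 1

#' Specify a dimensional-reduction method
#'
#' @param method "subc", "moa" or "spc".
#' @param centroids genes x centroids matrix (required for subc).
#' @param geneset character vector of gene ids (required for moa).
#' @param mtop number of genes kept by interaction-p feature selection
#'   (moa/spc).
#' @param K number of principal components (moa/spc; default 1).
#' @param moa_covariates for moa only: "pc" (default) feeds the selected genes
#'   into a K-component PC basis; "genes" uses the selected genes directly as
#'   mtop covariates.
#' @return a `feature_spec` object.
#' @export
feature_spec <- function(method = c("subc", "moa", "spc"), centroids = NULL,
                         geneset = NULL, mtop = NULL, K = 1,
                         moa_covariates = c("pc", "genes")) {
  method <- match.arg(method)
  moa_covariates <- match.arg(moa_covariates)
  if (method == "subc" && is.null(centroids))
    stopf("method 'subc' requires a centroid matrix")
  if (method == "moa" && is.null(geneset))
    stopf("method 'moa' requires a gene list")
  if (method %in% c("moa", "spc")) {
    if (is.null(mtop) || mtop < 1) stopf("method '%s' requires mtop >= 1", method)
    if (K < 1) stopf("K must be >= 1")
  }
  if (!is.null(centroids)) validate_centroids(centroids)
  structure(list(method = method, centroids = centroids, geneset = geneset,
                 mtop = if (is.null(mtop)) NULL else as.integer(mtop),
                 K = as.integer(K), moa_covariates = moa_covariates),
            class = "feature_spec")
}

#' Project expression profiles onto subtype centroids
#'
#' For every sample, computes the Pearson correlation of its profile with each
#' centroid over the genes the two share, clips it to +/-(1 - 1e-6), and
#' applies the Fisher transform `zeta = atanh(r)`. Column means over the
#' provided (training) samples are stored for the mean-centered covariates.
#'
#' @param expr expression matrix.
#' @param centroids genes x centroids matrix; >= 3 genes must overlap `expr`.
#' @return object of class `subtype_features`: `zeta` (samples x centroids),
#'   `centering_means`, `gene_ids` (the overlap used), `centroids` (restricted
#'   to the overlap, for projecting new samples).
#' @export
subc_project <- function(expr, centroids) {
  validate_expression(expr)
  validate_centroids(centroids)
  overlap <- intersect(rownames(centroids), rownames(expr))
  if (length(overlap) < 3)
    stopf("only %d gene(s) shared with the centroids; need >= 3", length(overlap))
  C <- centroids[overlap, , drop = FALSE]
  X <- expr[overlap, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance profile on the overlap genes for sample(s): %s",
          paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
  csd <- apply(C, 2, stats::sd)
  if (any(csd == 0)) stopf("centroid constant on the overlap genes")
  r <- stats::cor(X, C)                       # samples x centroids
  zeta <- atanh(pmin(pmax(r, -CLIP_R), CLIP_R))
  structure(list(zeta = zeta,
                 centering_means = colMeans(zeta),
                 gene_ids = overlap,
                 centroids = C),
            class = "subtype_features")
}

#' Rank genes by the treatment-interaction p-value of single-gene Cox models
#'
#' For each gene fits the univariate interaction model
#' `log-hazard = beta0*z + beta1*x + gamma*z*x` and ranks genes by the Wald
#' p-value of the interaction coefficient gamma (ascending). Ties break by
#' |gamma| descending, then gene id. Genes whose fit fails or does not
#' converge are assigned p = 1 and flagged, not dropped.
#'
#' @param expr expression matrix (typically standardized).
#' @param clin aligned clinical table; both arms must have >= 1 event.
#' @return data.frame with columns `gene_id`, `p_value`, `gamma`, `flagged`,
#'   ordered by rank.
#' @export
rank_genes_by_interaction <- function(expr, clin) {
  validate_expression(expr)
  validate_clinical(clin)
  if (ncol(expr) != nrow(clin)) stopf("expression and clinical table not aligned")
  for (a in c(0, 1)) {
    if (!any(clin$event[clin$arm == a] == 1))
      stopf("arm %d has no observed events", a)
  }
  z <- clin$arm
  p <- nrow(expr)
  pv <- rep(1, p); gm <- rep(0, p); flagged <- logical(p)
  for (i in seq_len(p)) {
    x <- expr[i, ]
    if (stats::sd(x) == 0) { flagged[i] <- TRUE; next }
    fit <- .coxfit(cbind(z, x, z * x), clin$pfs_months, clin$event)
    ok <- !is.null(fit) && isTRUE(fit$converged) && !anyNA(fit$coefficients) &&
      is.finite(fit$var[3, 3]) && fit$var[3, 3] > 0
    if (!ok) { flagged[i] <- TRUE; next }
    g <- fit$coefficients[3]
    pv[i] <- 2 * stats::pnorm(-abs(g / sqrt(fit$var[3, 3])))
    gm[i] <- g
  }
  ord <- order(pv, -abs(gm), rownames(expr))
  data.frame(gene_id = rownames(expr)[ord], p_value = pv[ord], gamma = gm[ord],
             flagged = flagged[ord], stringsAsFactors = FALSE)
}

#' Keep the top mtop genes of an interaction ranking
#' @param ranked data.frame from [rank_genes_by_interaction()].
#' @param mtop integer in 1..nrow(ranked).
#' @return character vector of mtop gene ids.
#' @export
select_top <- function(ranked, mtop) {
  if (length(mtop) != 1 || is.na(mtop) || mtop < 1 || mtop > nrow(ranked))
    stopf("mtop must lie in 1..%d", nrow(ranked))
  ranked$gene_id[seq_len(mtop)]
}

#' Fit a principal-component basis on a gene subset
#'
#' The components are the top-K right singular directions of the
#' gene-restricted, gene-centered data (genes as variables, samples as
#' observations). Signs are fixed so each component's largest-magnitude
#' loading is positive, making projections reproducible across runs.
#'
#' @param expr expression matrix (training samples).
#' @param genes character vector of gene ids; the overlap with `expr` must be
#'   at least K.
#' @param K number of components.
#' @return object of class `pc_basis`: `gene_ids`, `components` (genes x K,
#'   orthonormal), `centers` (training gene means), `K`.
#' @export
fit_pc_basis <- function(expr, genes, K = 1) {
  validate_expression(expr)
  sub <- intersect_genes(expr, genes)
  if (nrow(sub) < K) stopf("only %d gene(s) available; need >= K = %d", nrow(sub), K)
  centers <- rowMeans(sub)
  Y <- t(sub - centers)                        # samples x genes, column-centered
  sv <- svd(Y, nu = 0, nv = min(dim(Y)))
  rank_avail <- sum(sv$d > sv$d[1] * 1e-12)
  if (K > rank_avail)
    stopf("K = %d exceeds the available rank %d", K, rank_avail)
  U <- sv$v[, seq_len(K), drop = FALSE]
  for (l in seq_len(K)) {
    j <- which.max(abs(U[, l]))
    if (U[j, l] < 0) U[, l] <- -U[, l]
  }
  dimnames(U) <- list(rownames(sub), paste0("PC", seq_len(K)))
  structure(list(gene_ids = rownames(sub), components = U,
                 centers = centers, K = K),
            class = "pc_basis")
}

#' Fit the dimensional reduction of a feature spec on training data
#'
#' Dispatches on the spec's method and returns a fitted object that
#' [project_features()] can apply to any sample set. Selection, PC bases and
#' centering means are computed from `expr`/`clin` only.
#'
#' @param expr training expression matrix.
#' @param clin training clinical table (needed for moa/spc gene ranking).
#' @param spec a [feature_spec()].
#' @param ranked optional precomputed ranking (as from
#'   [rank_genes_by_interaction()] on the same training data) reused across
#'   mtop values during sweeps.
#' @return object of class `feature_fit`.
#' @export
fit_features <- function(expr, clin = NULL, spec, ranked = NULL) {
  stopifnot(inherits(spec, "feature_spec"))
  if (spec$method == "subc") {
    sf <- subc_project(expr, spec$centroids)
    return(structure(list(spec = spec, subc = sf), class = "feature_fit"))
  }
  if (is.null(clin)) stopf("method '%s' needs a clinical table", spec$method)
  pool <- if (spec$method == "moa") intersect_genes(expr, spec$geneset) else expr
  pool <- pool[apply(pool, 1, stats::sd) > 0, , drop = FALSE]
  if (is.null(ranked)) ranked <- rank_genes_by_interaction(pool, clin)
  mtop <- min(spec$mtop, nrow(ranked))
  genes <- select_top(ranked, mtop)
  if (spec$method == "moa" && spec$moa_covariates == "genes") {
    sub <- pool[genes, , drop = FALSE]
    return(structure(list(spec = spec, genes = genes,
                          centers = rowMeans(sub)), class = "feature_fit"))
  }
  basis <- fit_pc_basis(pool, genes, K = min(spec$K, length(genes)))
  structure(list(spec = spec, genes = genes, basis = basis),
            class = "feature_fit")
}

#' Project samples onto fitted features
#'
#' Maps samples into the trained covariate space with training-derived
#' centering means and components; nothing is refit on the projected data.
#'
#' @param fit a `feature_fit` from [fit_features()].
#' @param expr expression matrix to project (any sample set covering the
#'   fit's genes).
#' @return samples x K numeric covariate matrix with sample rownames.
#' @export
project_features <- function(fit, expr) {
  stopifnot(inherits(fit, "feature_fit"))
  validate_expression(expr)
  spec <- fit$spec
  if (spec$method == "subc") {
    sf <- fit$subc
    miss <- setdiff(sf$gene_ids, rownames(expr))
    if (length(miss))
      stopf("expression lacks %d gene(s) of the fitted centroid overlap", length(miss))
    X <- expr[sf$gene_ids, , drop = FALSE]
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stopf("zero-variance profile on overlap genes for sample(s): %s",
            paste(utils::head(colnames(X)[sds == 0], 5), collapse = ", "))
    r <- stats::cor(X, sf$centroids)
    zeta <- atanh(pmin(pmax(r, -CLIP_R), CLIP_R))
    return(sweep(zeta, 2, sf$centering_means))
  }
  if (!is.null(fit$basis)) {
    b <- fit$basis
    miss <- setdiff(b$gene_ids, rownames(expr))
    if (length(miss)) stopf("expression lacks %d fitted gene(s)", length(miss))
    X <- expr[b$gene_ids, , drop = FALSE] - b$centers
    return(t(X) %*% b$components)
  }
  miss <- setdiff(fit$genes, rownames(expr))
  if (length(miss)) stopf("expression lacks %d selected gene(s)", length(miss))
  t(expr[fit$genes, , drop = FALSE] - fit$centers)
}
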