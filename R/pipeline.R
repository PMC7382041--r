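# End-to-end orchestration: load or accept data, preprocess, cross-validate,
# evaluate, decide, resample, and write a run directory of TSV/JSON outputs
# with a machine-readable provenance record.

#' Run the full signature pipeline
#'
#' Sequences the whole analysis: sample alignment, optional quantile
#' normalization and standardization, pre-validated k-fold cross-validation of
#' the chosen feature method, the hROC and area between curves, threshold
#' choice (ad hoc or by objective-function minimization), the patient
#' selection matrix and KM exports, bootstrap resampling with predictive risk,
#' and (optionally) the single-permutation negative control. All randomness
#' derives from one master seed recorded in the provenance file.
#'
#' @param expr expression matrix (or a path readable by [read_expression()]).
#' @param clin clinical table (or a path readable by [read_clinical()]).
#' @param spec a [feature_spec()].
#' @param out_dir output directory (created if absent); set NULL to skip
#'   writing files.
#' @param threshold fixed dLHR decision threshold, or NULL to minimize the
#'   objective function over the hROC.
#' @param qmin lower bound on the sensitive fraction when optimizing the
#'   threshold (e.g. 0.25 to keep trial accrual feasible).
#' @param k folds.
#' @param B bootstrap replicates (0 skips the bootstrap).
#' @param permute also run the permutation negative control.
#' @param quantile_norm apply quantile normalization first.
#' @param standardize_mode "global" (default: standardize once on all
#'   samples), "fold" (refit per training fold) or "none".
#' @param seed master seed.
#' @return (invisibly) a list with scores, hroc, abc, threshold, split, psm,
#'   km, bootstrap, permutation and provenance.
#' @export
run_pipeline <- function(expr, clin, spec, out_dir = NULL, threshold = NULL,
                         qmin = 0, k = 5, B = 0, permute = FALSE,
                         quantile_norm = FALSE,
                         standardize_mode = c("global", "fold", "none"),
                         seed = 1) {
  standardize_mode <- match.arg(standardize_mode)
  stopifnot(inherits(spec, "feature_spec"))
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(clin)) clin <- read_clinical(clin)
  al <- align_samples(expr, clin)
  expr <- al$expr; clin <- al$clin
  if (quantile_norm) expr <- quantile_normalize(expr)
  if (standardize_mode == "global") expr <- standardize(expr)$expr
  fold_std <- standardize_mode == "fold"
  seeds <- derive_seeds(seed, 3L)

  folds <- make_folds(clin, k, seeds[1])
  scores <- prevalidate(expr, clin, spec, folds, standardize_fold = fold_std)
  hroc <- hroc_sweep(scores, clin)
  abc <- area_between_curves(hroc)
  profile <- tryCatch(objective_phi(hroc, qmin = qmin), error = function(e) NULL)
  if (is.null(threshold)) {
    if (is.null(profile)) stopf("cannot optimize threshold: %s",
                                "no defined hROC points")
    threshold <- profile$threshold_star
  }
  split <- split_at_threshold(scores, threshold)
  psm <- patient_selection_matrix(clin, split)
  km <- km_export(clin, split$labels)
  scatter <- survival_scatter(scores, clin)

  boot <- NULL
  if (B > 0)
    boot <- bootstrap_signature(expr, clin, spec, threshold, B, k,
                                seed = seeds[2], standardize_fold = fold_std)
  perm <- NULL
  if (permute) {
    if (B < 1) stopf("permutation control requires B >= 1")
    perm <- permutation_control(expr, clin, spec, threshold, B, k,
                                seed = seeds[3], standardize_fold = fold_std)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("predsig")),
    r_version = R.version.string,
    n = nrow(clin), p = nrow(expr), k = k, B = B,
    method = spec$method, mtop = spec$mtop, K = spec$K,
    threshold = threshold, qmin = qmin, permute = permute,
    quantile_norm = quantile_norm, standardize_mode = standardize_mode,
    master_seed = seed, derived_seeds = as.list(seeds))

  result <- list(scores = scores, hroc = hroc, abc = abc, profile = profile,
                 threshold = threshold, split = split, psm = psm, km = km,
                 scatter = scatter, bootstrap = boot, permutation = perm,
                 provenance = provenance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(scores, "prevalidated_scores.tsv")
    wt(hroc$points, "hroc.tsv")
    wt(scatter, "survival_scatter.tsv")
    wt(km, "km_curves.tsv")
    wt(data.frame(cell = outer(rownames(psm$medians), colnames(psm$medians),
                               paste, sep = ":"),
                  median_pfs = as.vector(psm$medians),
                  n = as.vector(psm$counts)), "psm.tsv")
    summary_json <- list(
      abc = abc$abc, threshold = threshold, q = split$q,
      n_S = split$n_S, n_R = split$n_R,
      hR_all = hroc$hR_all$hazard_ratio,
      hR_S = psm$col_margins$S$hazard_ratio,
      pR_S = psm$col_margins$S$p_value,
      hR_R = psm$col_margins$R$hazard_ratio,
      pR_R = psm$col_margins$R$p_value,
      q_star = if (!is.null(profile)) profile$q_star else NULL,
      p_risk = if (!is.null(boot)) boot$p_risk else NULL,
      p_risk_permuted = if (!is.null(perm)) perm$bootstrap$p_risk else NULL,
      permutation_p = if (!is.null(perm)) perm$null$p_value else NULL)
    jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (!is.null(boot))
      wt(data.frame(hS_star = boot$hS_star, hR_star = boot$hR_star,
                    nS_star = boot$nS_star, abc_star = boot$abc_star,
                    rho_star = boot$rho_star), "bootstrap_replicates.tsv")
  }
  invisible(result)
}
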