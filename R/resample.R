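# Pre-validated k-fold cross-validation, bootstrap resampling with nested CV,
# the predictive risk pRisk = Pr(Abc < 0), and the single-permutation null.
#
# Pre-validation: for each fold, features and the interaction Cox model are
# fitted on the out-of-fold samples only, and the held-out fold is scored
# with that model; the pooled n scores behave like scores from an independent
# test set.

#' Random arm-stratified fold assignment
#'
#' Deals a single round-robin cycle of fold labels over the arm-0 samples
#' followed by the arm-1 samples (each shuffled), so overall fold sizes differ
#' by at most one and per-arm counts are balanced too. Falls back to
#' unstratified assignment (with a warning) when an arm is smaller than k.
#'
#' @param clin clinical table.
#' @param k number of folds (2..n).
#' @param seed integer seed; the same seed always reproduces the assignment.
#' @return a `fold_assignment`: `sample_id`, `fold_id` (1..k), `k`, `seed`.
#' @export
make_folds <- function(clin, k, seed) {
  validate_clinical(clin)
  n <- nrow(clin)
  if (k < 2 || k > n) stopf("k must lie in 2..n")
  fold_id <- integer(n)
  with_seed(seed, {
    labels <- rep_len(sample.int(k), n)
    counts <- table(factor(clin$arm, levels = c(0, 1)))
    if (min(counts) >= k && min(counts) > 0) {
      ord <- c(sample(which(clin$arm == 0)), sample(which(clin$arm == 1)))
    } else {
      warnf("an arm has fewer than k samples; using unstratified folds")
      ord <- sample.int(n)
    }
    fold_id[ord] <- labels
  })
  structure(list(sample_id = clin$sample_id, fold_id = fold_id,
                 k = as.integer(k), seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Pre-validated cross-validation scores
#'
#' For each fold, fits the feature reduction and the interaction Cox model on
#' the out-of-fold samples only, then scores the held-out fold's dLHR with
#' that model. All n scores are pooled with fold provenance. With
#' `standardize_fold = TRUE`, per-gene standardization is also refit inside
#' each training fold and applied to the held-out samples (the strictly
#' leakage-free variant); by default the caller is assumed to have
#' standardized globally beforehand.
#'
#' @param expr expression matrix, aligned with `clin`.
#' @param clin clinical table.
#' @param spec a [feature_spec()].
#' @param folds a [make_folds()] assignment over the same samples.
#' @param standardize_fold refit standardization per training fold.
#' @return data.frame with columns `sample_id`, `dlhr`, `fold_id` in `clin`
#'   sample order; the per-fold Cox and feature fits are attached as
#'   attributes `"fold_fits"` and `"feature_fits"`.
#' @export
prevalidate <- function(expr, clin, spec, folds, standardize_fold = FALSE) {
  stopifnot(inherits(folds, "fold_assignment"))
  if (!identical(folds$sample_id, clin$sample_id))
    stopf("fold assignment does not match the clinical table")
  if (!identical(colnames(expr), clin$sample_id))
    stopf("expression and clinical table not aligned")
  n <- nrow(clin)
  scores <- rep(NA_real_, n)
  fold_fits <- feature_fits <- vector("list", folds$k)
  for (kk in seq_len(folds$k)) {
    test <- folds$fold_id == kk
    res <- tryCatch({
      etr <- expr[, !test, drop = FALSE]
      ete <- expr[, test, drop = FALSE]
      if (standardize_fold) {
        st <- standardize(etr)
        etr <- st$expr
        ete <- apply_standardization(ete[rownames(etr), , drop = FALSE], st$params)
      }
      ffit <- fit_features(etr, clin[!test, , drop = FALSE], spec)
      ctr <- project_features(ffit, etr)
      cfit <- fit_interaction_cox(ctr, clin[!test, , drop = FALSE])
      cte <- project_features(ffit, ete)
      list(scores = dlhr(cfit, cte)$dlhr, cfit = cfit, ffit = ffit)
    }, error = function(e) e)
    if (inherits(res, "error"))
      stopf("training fit failed for fold %d: %s", kk, conditionMessage(res))
    scores[test] <- res$scores
    fold_fits[[kk]] <- res$cfit
    feature_fits[[kk]] <- res$ffit
  }
  out <- data.frame(sample_id = clin$sample_id, dlhr = scores,
                    fold_id = folds$fold_id, stringsAsFactors = FALSE)
  attr(out, "fold_fits") <- fold_fits
  attr(out, "feature_fits") <- feature_fits
  out
}

# One cross-validated evaluation: prevalidated scores -> fixed-threshold
# split + group comparisons + hROC/Abc. Shared by bootstrap and pipeline.
.evaluate_once <- function(expr, clin, spec, threshold, folds,
                           standardize_fold = FALSE, min_n = 5) {
  scores <- prevalidate(expr, clin, spec, folds, standardize_fold)
  split <- split_at_threshold(scores, threshold)
  cS <- compare_arms(clin, names(split$labels)[split$labels == "S"])
  cR <- compare_arms(clin, names(split$labels)[split$labels == "R"])
  hroc <- hroc_sweep(scores, clin, min_n = min_n)
  abc <- tryCatch(area_between_curves(hroc)$abc, error = function(e) NA_real_)
  list(scores = scores, split = split, cS = cS, cR = cR, hroc = hroc,
       abc = abc, rho = selectivity_index(cS, cR))
}

.pct_ci <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(c(NA_real_, NA_real_))
  unname(stats::quantile(x, c(0.025, 0.975), type = 7))
}

#' Bootstrap resampling of the full cross-validated signature
#'
#' Repeats, B times: resample n patients with replacement (duplicates kept as
#' distinct instances), regenerate the k folds from scratch, rerun the
#' pre-validated cross-validation, split at the fixed threshold, and record
#' hR(S)*, hR(R)*, n(S)*, Abc* and rho*. By default all copies of a source
#' patient share a fold (`duplicate_folds = "grouped"`): letting clones
#' straddle the train/test boundary leaks each patient's own outcome into the
#' model that scores it, which a permuted-label control exposes as optimism
#' (Abc* biased above 0). `duplicate_folds = "free"` lets copies land in
#' different folds. Summaries
#' are medians with 2.5/97.5 percentile intervals; the predictive risk is
#' `pRisk = Pr(Abc* < 0)`, the estimated probability that the signature fails
#' under generalization. Replicates where a quantity is undefined are dropped
#' from that quantity's summary only; replicates that fail outright are
#' counted in `n_failed`.
#'
#' @param expr expression matrix aligned with `clin`.
#' @param clin clinical table.
#' @param spec a [feature_spec()].
#' @param threshold fixed dLHR decision threshold.
#' @param B number of bootstrap replicates.
#' @param k folds per replicate.
#' @param seed master seed; per-replicate streams derive from it.
#' @param standardize_fold passed to [prevalidate()].
#' @param duplicate_folds "grouped" (default) or "free"; see Details.
#' @return a `bootstrap_summary`: replicate vectors `hS_star`, `hR_star`,
#'   `nS_star`, `abc_star`, `rho_star`; `medians` and `ci` per quantity;
#'   `p_risk`; `n_failed`; `B`.
#' @export
bootstrap_signature <- function(expr, clin, spec, threshold, B, k = 5, seed = 1,
                                standardize_fold = FALSE,
                                duplicate_folds = c("grouped", "free")) {
  duplicate_folds <- match.arg(duplicate_folds)
  if (B < 1) stopf("B must be >= 1")
  n <- nrow(clin)
  seeds <- derive_seeds(seed, 2L * B)
  draw_seeds <- seeds[seq_len(B)]
  fold_seeds <- seeds[B + seq_len(B)]
  hS <- hR <- nS <- abc <- rho <- rep(NA_real_, B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      idx <- with_seed(draw_seeds[b], sample.int(n, n, replace = TRUE))
      ids <- make.unique(clin$sample_id[idx], sep = "#")
      clin_b <- clin[idx, , drop = FALSE]
      clin_b$sample_id <- ids
      rownames(clin_b) <- NULL
      expr_b <- expr[, idx, drop = FALSE]
      colnames(expr_b) <- ids
      folds <- if (duplicate_folds == "grouped") {
        upat <- unique(idx)
        fu <- suppressWarnings(
          make_folds(clin[upat, , drop = FALSE], k, fold_seeds[b]))
        structure(list(sample_id = ids,
                       fold_id = fu$fold_id[match(idx, upat)],
                       k = as.integer(k), seed = fold_seeds[b]),
                  class = "fold_assignment")
      } else {
        make_folds(clin_b, k, fold_seeds[b])
      }
      suppressWarnings(
        .evaluate_once(expr_b, clin_b, spec, threshold, folds, standardize_fold))
    }, error = function(e) e)
    if (inherits(res, "error")) { n_failed <- n_failed + 1L; next }
    if (res$cS$defined) hS[b] <- res$cS$hazard_ratio
    if (res$cR$defined) hR[b] <- res$cR$hazard_ratio
    nS[b] <- res$split$n_S
    abc[b] <- res$abc
    if (is.finite(res$rho)) rho[b] <- res$rho
  }
  if (n_failed == B) stopf("all %d bootstrap replicates failed", B)
  quantities <- list(hS_star = hS, hR_star = hR, nS_star = nS,
                     abc_star = abc, rho_star = rho)
  structure(c(quantities, list(
    medians = vapply(quantities, function(x) stats::median(x, na.rm = TRUE), 0),
    ci = lapply(quantities, .pct_ci),
    p_risk = mean(abc[is.finite(abc)] < 0),
    n_failed = n_failed, B = as.integer(B), threshold = threshold, k = k,
    seed = as.integer(seed))), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("bootstrap: B = %d (%d failed), threshold = %.3g\n",
              x$B, x$n_failed, x$threshold))
  for (q in names(x$medians)) {
    ci <- x$ci[[q]]
    cat(sprintf("  %-9s median %.3g [%.3g, %.3g]\n", q, x$medians[[q]], ci[1], ci[2]))
  }
  cat(sprintf("  pRisk = Pr(Abc* < 0) = %.3g\n", x$p_risk))
  invisible(x)
}

#' Single-permutation negative control with bootstrap null distribution
#'
#' Permutes the expression-to-clinical linkage once (a single fixed
#' permutation drawn from the seed), runs the full bootstrap on the permuted
#' data to obtain a null distribution of Abc*, and computes the one-sided
#' empirical p-value `P = Pr(Abc_null > Abc_obs)` of the observed
#' (non-permuted, non-bootstrapped) cross-validated Abc against that null.
#'
#' @inheritParams bootstrap_signature
#' @return list with `bootstrap` (the `bootstrap_summary` on permuted data)
#'   and `null` (list with `abc_null`, `abc_obs`, `p_value`).
#' @export
permutation_control <- function(expr, clin, spec, threshold, B, k = 5, seed = 1,
                                standardize_fold = FALSE,
                                duplicate_folds = c("grouped", "free")) {
  duplicate_folds <- match.arg(duplicate_folds)
  seeds <- derive_seeds(seed, 3L)
  expr_perm <- permute_labels(expr, clin, seed = seeds[1])
  boot <- bootstrap_signature(expr_perm, clin, spec, threshold, B, k,
                              seed = seeds[2], standardize_fold = standardize_fold,
                              duplicate_folds = duplicate_folds)
  folds <- make_folds(clin, k, seed = seeds[3])
  obs <- suppressWarnings(
    .evaluate_once(expr, clin, spec, threshold, folds, standardize_fold))
  abc_null <- boot$abc_star[is.finite(boot$abc_star)]
  p_value <- if (length(abc_null) && is.finite(obs$abc))
    mean(abc_null > obs$abc) else NA_real_
  list(bootstrap = boot,
       null = list(abc_null = abc_null, abc_obs = obs$abc, p_value = p_value))
}
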