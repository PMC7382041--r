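# Threshold selection and decision summaries: the objective function phi(q),
# the mtop feature-count sweep, the patient selection matrix (PSM) and
# Kaplan-Meier exports.

#' Objective function over the hROC for threshold selection
#'
#' Evaluates, at every hROC point where both group hazard ratios are defined,
#' the cost function
#' `phi(q) = -q * (h0 - hS(q)) + (1 - q) * max(1 - hR(q), 0)`,
#' where h0 is the all-patients hazard ratio. The first term rewards treatment
#' benefit concentrated in the sensitive fraction q; the second charges for
#' denying beneficial treatment to the resistant fraction (gated out when
#' hR(q) > 1). The optimal split `q*` minimizes phi over the defined grid (no
#' interpolation; ties break to the smallest q), optionally inside a box
#' constraint such as the trial-accrual bound q >= 0.25.
#'
#' @param hroc an `hroc` object.
#' @param qmin,qmax optional box constraint on q.
#' @return an `objective_profile`: `q_grid`, `phi`, `h0`, `hS_of_q`,
#'   `hR_of_q`, `q_star`, `threshold_star`.
#' @export
objective_phi <- function(hroc, qmin = 0, qmax = 1) {
  stopifnot(inherits(hroc, "hroc"))
  if (!hroc$hR_all$defined) stopf("all-patients hazard ratio undefined")
  h0 <- hroc$hR_all$hazard_ratio
  pts <- hroc$points
  ok <- pts$def_S & pts$def_R
  if (!any(ok)) stopf("no hROC points with both hazard ratios defined")
  q <- pts$q[ok]; hS <- pts$hR_S[ok]; hR <- pts$hR_R[ok]; thr <- pts$threshold[ok]
  phi <- -q * (h0 - hS) + (1 - q) * pmax(1 - hR, 0)
  inbox <- q >= qmin & q <= qmax
  if (!any(inbox)) stopf("no defined q-points inside [%g, %g]", qmin, qmax)
  cand <- which(inbox)
  star <- cand[which.min(phi[cand])]      # which.min takes the first (smallest q)
  structure(list(q_grid = q, phi = phi, h0 = h0, hS_of_q = hS, hR_of_q = hR,
                 q_star = q[star], threshold_star = thr[star],
                 phi_star = phi[star]),
            class = "objective_profile")
}

#' @export
print.objective_profile <- function(x, ...) {
  cat(sprintf("phi optimum: q* = %.3g at threshold %.3g (phi = %.4g, h0 = %.3g)\n",
              x$q_star, x$threshold_star, x$phi_star, x$h0))
  invisible(x)
}

#' Sweep the number of selected genes and score each model by Abc
#'
#' For each value of mtop in the grid, reruns the pre-validated
#' cross-validation (with a fixed fold assignment) and records the area
#' between curves. The per-fold interaction-p gene rankings do not depend on
#' mtop and are computed once and reused across the grid. A failure at a
#' single mtop is recorded as NA, not fatal.
#'
#' @param expr expression matrix aligned with `clin`.
#' @param clin clinical table.
#' @param spec_template a [feature_spec()] of method "moa" or "spc" whose mtop
#'   is overridden along the grid.
#' @param mtop_grid integer vector of candidate mtop values.
#' @param folds_seed seed for the shared fold assignment.
#' @param k number of folds.
#' @param min_n per-arm minimum for defined hROC points.
#' @return a `sweep_result`: `mtop_grid`, `abc_per_mtop`, `best_mtop` (ties
#'   break to the smallest mtop).
#' @export
optimize_mtop <- function(expr, clin, spec_template, mtop_grid, folds_seed,
                          k = 5, min_n = 5) {
  stopifnot(inherits(spec_template, "feature_spec"))
  if (spec_template$method == "subc") stopf("mtop sweep applies to moa/spc only")
  mtop_grid <- as.integer(mtop_grid)
  folds <- make_folds(clin, k, folds_seed)
  # per-fold training pools and rankings, shared across the grid
  pools <- rankings <- vector("list", k)
  for (kk in seq_len(k)) {
    tr <- folds$fold_id != kk
    pool <- if (spec_template$method == "moa")
      intersect_genes(expr[, tr, drop = FALSE], spec_template$geneset)
    else expr[, tr, drop = FALSE]
    pool <- pool[apply(pool, 1, stats::sd) > 0, , drop = FALSE]
    pools[[kk]] <- rownames(pool)
    rankings[[kk]] <- rank_genes_by_interaction(pool, clin[tr, , drop = FALSE])
  }
  abcs <- rep(NA_real_, length(mtop_grid))
  for (m in seq_along(mtop_grid)) {
    spec_m <- spec_template
    spec_m$mtop <- mtop_grid[m]
    res <- tryCatch({
      scores <- rep(NA_real_, nrow(clin))
      for (kk in seq_len(k)) {
        tr <- folds$fold_id != kk
        etr <- expr[pools[[kk]], tr, drop = FALSE]
        ffit <- fit_features(etr, clin[tr, , drop = FALSE], spec_m,
                             ranked = rankings[[kk]])
        cfit <- fit_interaction_cox(project_features(ffit, etr),
                                    clin[tr, , drop = FALSE])
        scores[!tr] <- dlhr(cfit, project_features(
          ffit, expr[, !tr, drop = FALSE]))$dlhr
      }
      sc <- data.frame(sample_id = clin$sample_id, dlhr = scores)
      area_between_curves(hroc_sweep(sc, clin, min_n = min_n))$abc
    }, error = function(e) NA_real_)
    abcs[m] <- res
  }
  if (all(is.na(abcs))) stopf("every mtop in the grid failed")
  best <- mtop_grid[which.max(replace(abcs, is.na(abcs), -Inf))]
  structure(list(mtop_grid = mtop_grid, abc_per_mtop = abcs,
                 best_mtop = best), class = "sweep_result")
}

#' Rank competing models by their area between curves
#' @param models data.frame with columns `name` and `abc` (one row per model),
#'   or a named numeric vector of Abc values.
#' @return data.frame ordered by decreasing Abc (ties keep name order).
#' @export
compare_models <- function(models) {
  if (is.numeric(models))
    models <- data.frame(name = names(models), abc = unname(models),
                         stringsAsFactors = FALSE)
  if (nrow(models) < 1) stopf("need at least one model")
  out <- models[order(-models$abc, models$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Kaplan-Meier median: smallest time with S(t) <= 0.5; NA when unreached.
.km_median <- function(time, event) {
  if (!length(time)) return(NA_real_)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  idx <- which(sf$surv <= 0.5)
  if (!length(idx)) NA_real_ else sf$time[min(idx)]
}

#' Patient selection matrix
#'
#' The 2 x 2 {treatment arm x response group} contingency summary around a
#' threshold split: Kaplan-Meier median PFS per cell (including All margins),
#' patient counts, hazard-ratio margins and p-values. Column margins compare
#' arms within each response group (the predictive reading); row margins
#' compare S versus R within each arm (the prognostic reading). `delta_pfs`
#' is the experimental-minus-control median gain per response group (NA when
#' a median is unreached).
#'
#' @param clin clinical table.
#' @param split a [split_at_threshold()] covering all samples in `clin`.
#' @return a `psm_table`: `medians` and `counts` (3 x 3 matrices with rows
#'   control/experimental/all and columns R/S/all), `col_margins` (per-group
#'   arm comparisons), `row_margins` (per-arm S-vs-R comparisons),
#'   `delta_pfs`.
#' @export
patient_selection_matrix <- function(clin, split) {
  validate_clinical(clin)
  stopifnot(inherits(split, "threshold_split"))
  lab <- split$labels[clin$sample_id]
  if (anyNA(lab)) stopf("split does not cover all clinical samples")
  arms <- list(control = 0, experimental = 1, all = c(0, 1))
  grps <- list(R = "R", S = "S", all = c("R", "S"))
  medians <- counts <- matrix(NA_real_, 3, 3,
                              dimnames = list(names(arms), names(grps)))
  for (a in seq_along(arms)) for (g in seq_along(grps)) {
    sel <- clin$arm %in% arms[[a]] & lab %in% grps[[g]]
    counts[a, g] <- sum(sel)
    medians[a, g] <- .km_median(clin$pfs_months[sel], clin$event[sel])
  }
  col_margins <- lapply(grps, function(g) {
    sel <- lab %in% g
    .compare_binary(clin$pfs_months[sel], clin$event[sel], clin$arm[sel])
  })
  row_margins <- lapply(arms, function(a) {
    sel <- clin$arm %in% a
    .compare_binary(clin$pfs_months[sel], clin$event[sel],
                    as.numeric(lab[sel] == "S"))
  })
  delta_pfs <- c(R = medians["experimental", "R"] - medians["control", "R"],
                 S = medians["experimental", "S"] - medians["control", "S"])
  structure(list(threshold = split$threshold, medians = medians,
                 counts = counts, col_margins = col_margins,
                 row_margins = row_margins, delta_pfs = delta_pfs),
            class = "psm_table")
}

#' @export
print.psm_table <- function(x, ...) {
  cat(sprintf("patient selection matrix at threshold %.3g\n", x$threshold))
  cat("median PFS (months):\n"); print(round(x$medians, 2))
  cat("counts:\n"); print(x$counts)
  cat(sprintf("delta PFS (experimental - control): R = %.3g, S = %.3g\n",
              x$delta_pfs["R"], x$delta_pfs["S"]))
  for (g in names(x$col_margins)) {
    m <- x$col_margins[[g]]
    if (m$defined)
      cat(sprintf("arm comparison in %s: hR = %.3g, p = %.3g\n",
                  g, m$hazard_ratio, m$p_value))
  }
  invisible(x)
}

#' Export Kaplan-Meier step functions per group and arm
#'
#' @param clin clinical table.
#' @param groups named character vector (sample_id -> group label); defaults
#'   to a single group containing everyone.
#' @return data.frame with columns group, arm, time, n_risk, n_event,
#'   n_censor, surv — one row per distinct event/censoring time per
#'   group x arm stratum.
#' @export
km_export <- function(clin, groups = NULL) {
  validate_clinical(clin)
  if (is.null(groups))
    groups <- stats::setNames(rep("all", nrow(clin)), clin$sample_id)
  g <- groups[clin$sample_id]
  if (anyNA(g)) stopf("groups do not cover all clinical samples")
  out <- list()
  for (gv in unique(g)) for (av in sort(unique(clin$arm[g == gv]))) {
    sel <- g == gv & clin$arm == av
    if (!any(sel)) next
    sf <- survival::survfit(
      survival::Surv(clin$pfs_months[sel], clin$event[sel]) ~ 1)
    out[[length(out) + 1L]] <- data.frame(
      group = gv, arm = av, time = sf$time, n_risk = sf$n.risk,
      n_event = sf$n.event, n_censor = sf$n.censor, surv = sf$surv,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
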