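# Evaluation statistics for the dLHR biomarker: threshold splits into
# sensitive (S) / relatively-resistant (R) groups, within-group arm hazard
# ratios, the hazard-ratio ROC (hROC) sweep, the area between curves (Abc)
# and the selectivity index.

#' Symmetrizing transform of a hazard ratio
#'
#' `sigma(h) = (h - 1)/(h + 1) = tanh(log(h)/2)`: strictly increasing, maps
#' (0, Inf) to (-1, 1) with `sigma(1) = 0` and `sigma(1/h) = -sigma(h)`. Areas
#' under hROC curves are computed on this scale so each is bounded by 1 in
#' magnitude and equal hazard ratios in both arms contribute 0.
#'
#' @param h positive hazard ratio(s).
#' @return transformed value(s) in (-1, 1).
#' @export
sigma_hr <- function(h) (h - 1) / (h + 1)

# Binary two-group survival comparison: hazard ratio of g = 1 relative to
# g = 0 from a univariate Cox model, Wald CI, and the Cox score test p-value
# (identical to the log-rank test for a binary grouping).
.compare_binary <- function(time, event, g, min_n = 1, min_events = 1,
                            conf = 0.95) {
  undefined <- function(n, ne) {
    structure(list(hazard_ratio = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p_value = NA_real_, n = n,
                   n_events = ne, defined = FALSE), class = "group_comparison")
  }
  n <- length(g); ne <- sum(event)
  for (lev in c(0, 1)) {
    sel <- g == lev
    if (sum(sel) < min_n || sum(event[sel]) < min_events)
      return(undefined(n, ne))
  }
  fit <- .coxfit(matrix(as.double(g), ncol = 1), time, event)
  if (is.null(fit) || !isTRUE(fit$converged) || anyNA(fit$coefficients) ||
      !is.finite(fit$var[1, 1]) || fit$var[1, 1] <= 0)
    return(undefined(n, ne))
  co <- fit$coefficients[1]
  se <- sqrt(fit$var[1, 1])
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  p <- stats::pchisq(fit$sctest %||% fit$score, df = 1, lower.tail = FALSE)
  structure(list(hazard_ratio = exp(co), ci_low = exp(co - zq * se),
                 ci_high = exp(co + zq * se), p_value = p, n = n,
                 n_events = ne, defined = TRUE), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$defined)
    cat(sprintf("hR = %.3g [%.3g, %.3g], p = %.3g (n = %d, %d events)\n",
                x$hazard_ratio, x$ci_low, x$ci_high, x$p_value, x$n, x$n_events))
  else cat(sprintf("hR undefined (n = %d, %d events)\n", x$n, x$n_events))
  invisible(x)
}

#' Compare treatment arms within a sample subset
#'
#' Univariate Cox model of the arm indicator (experimental relative to
#' control) within the subset: hR < 1 always indicates better survival in the
#' experimental arm. The p-value is the log-rank (Cox score) test. The result
#' is marked undefined when either arm has fewer than `min_n` subjects or
#' `min_events` events.
#'
#' @param clin clinical table.
#' @param subset optional character vector of sample ids (default all).
#' @param min_n,min_events per-arm minima for a defined comparison.
#' @return a `group_comparison` object.
#' @export
compare_arms <- function(clin, subset = NULL, min_n = 1, min_events = 1) {
  validate_clinical(clin)
  if (!is.null(subset)) {
    if (!length(subset)) stopf("empty subset")
    clin <- clin[clin$sample_id %in% subset, , drop = FALSE]
    if (!nrow(clin)) stopf("subset matches no samples")
  }
  .compare_binary(clin$pfs_months, clin$event, clin$arm,
                  min_n = min_n, min_events = min_events)
}

#' Split samples into sensitive / relatively-resistant groups at a threshold
#'
#' Sensitive (S) iff `dlhr <= threshold` (closed on the sensitive side),
#' relatively-resistant (R) otherwise.
#'
#' @param scores data.frame with columns `sample_id`, `dlhr`.
#' @param threshold dLHR decision threshold.
#' @return a `threshold_split`: `threshold`, `labels` (named "S"/"R" vector),
#'   `q` (fraction sensitive), `n_S`, `n_R`.
#' @export
split_at_threshold <- function(scores, threshold) {
  if (!all(is.finite(scores$dlhr))) stopf("scores must be finite")
  lab <- ifelse(scores$dlhr <= threshold, "S", "R")
  names(lab) <- scores$sample_id
  n_S <- sum(lab == "S")
  structure(list(threshold = threshold, labels = lab,
                 q = n_S / length(lab), n_S = n_S, n_R = length(lab) - n_S),
            class = "threshold_split")
}

#' Survival scatter plot data
#'
#' Long, plot-ready table of observed PFS against the (typically
#' cross-validated) dLHR: one row per patient with score, time, event and arm.
#'
#' @param scores data.frame with `sample_id`, `dlhr`.
#' @param clin clinical table covering the scored samples.
#' @return data.frame with columns sample_id, dlhr, pfs_months, event, arm.
#' @export
survival_scatter <- function(scores, clin) {
  validate_clinical(clin)
  idx <- match(scores$sample_id, clin$sample_id)
  if (anyNA(idx)) stopf("scored sample(s) missing from the clinical table")
  data.frame(sample_id = scores$sample_id, dlhr = scores$dlhr,
             pfs_months = clin$pfs_months[idx], event = clin$event[idx],
             arm = clin$arm[idx], stringsAsFactors = FALSE)
}

#' Sweep the decision threshold: the hazard-ratio ROC
#'
#' Sweeps the threshold through the score order, generating one point per
#' distinct binary partition (n + 1 points for tie-free scores, fewer with
#' ties). Each point records q (fraction sensitive) and the within-group arm
#' comparisons hR(S) and hR(R); a group's hazard ratio is only marked defined
#' when each arm contributes at least `min_n` subjects and `min_events`
#' events, since ratios from vanishingly small groups carry large variance.
#' The all-patients comparison hR(all) is computed once.
#'
#' @param scores data.frame with `sample_id`, `dlhr`.
#' @param clin aligned clinical table.
#' @param min_n,min_events per-arm minima for a defined point.
#' @return an `hroc` object: `points` (data.frame of threshold, q, n_S, hR_S,
#'   p_S, def_S, hR_R, p_R, def_R) and `hR_all` (a `group_comparison`).
#' @export
hroc_sweep <- function(scores, clin, min_n = 5, min_events = 1) {
  validate_clinical(clin)
  idx <- match(scores$sample_id, clin$sample_id)
  if (anyNA(idx)) stopf("scored sample(s) missing from the clinical table")
  time <- clin$pfs_months[idx]; event <- clin$event[idx]; arm <- clin$arm[idx]
  if (!any(event[arm == 0] == 1) || !any(event[arm == 1] == 1))
    stopf("need >= 1 event in each arm overall")
  s <- scores$dlhr
  thresholds <- c(-Inf, sort(unique(s)))
  n <- length(s)
  pts <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    inS <- s <= thresholds[i]
    cS <- .compare_binary(time[inS], event[inS], arm[inS], min_n, min_events)
    cR <- .compare_binary(time[!inS], event[!inS], arm[!inS], min_n, min_events)
    pts[[i]] <- data.frame(
      threshold = thresholds[i], q = sum(inS) / n, n_S = sum(inS),
      hR_S = cS$hazard_ratio, p_S = cS$p_value, def_S = cS$defined,
      hR_R = cR$hazard_ratio, p_R = cR$p_value, def_R = cR$defined)
  }
  structure(list(points = do.call(rbind, pts),
                 hR_all = .compare_binary(time, event, arm),
                 n = n),
            class = "hroc")
}

#' @export
print.hroc <- function(x, ...) {
  cat(sprintf("hROC: %d partitions over %d samples; hR(all) = %.3g\n",
              nrow(x$points), x$n,
              if (x$hR_all$defined) x$hR_all$hazard_ratio else NA))
  invisible(x)
}

#' Area between the hROC curves
#'
#' Both curves are mapped through the symmetrizing transform [sigma_hr()] and
#' integrated by the trapezoidal rule over the q-points where both are
#' defined; `Abc = A_hR - A_hS`. Positive Abc means the resistant-group curve
#' sits above the sensitive-group curve (hR(R) > hR(S)) over most of the
#' sweep, i.e. the biomarker selects patients who genuinely benefit more.
#'
#' @param hroc an `hroc` object.
#' @return an `abc_result`: `A_hR`, `A_hS`, `abc`, `q_support` (integration
#'   interval actually used), `n_points`.
#' @export
area_between_curves <- function(hroc) {
  stopifnot(inherits(hroc, "hroc"))
  pts <- hroc$points
  ok <- pts$def_S & pts$def_R
  if (sum(ok) < 2)
    stopf("fewer than 2 q-points where both curves are defined")
  q <- pts$q[ok]
  sR <- sigma_hr(pts$hR_R[ok])
  sS <- sigma_hr(pts$hR_S[ok])
  dq <- diff(q)
  A_hR <- sum(dq * (utils::head(sR, -1) + utils::tail(sR, -1)) / 2)
  A_hS <- sum(dq * (utils::head(sS, -1) + utils::tail(sS, -1)) / 2)
  structure(list(A_hR = A_hR, A_hS = A_hS, abc = A_hR - A_hS,
                 q_support = range(q), n_points = sum(ok)),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("Abc = %.4f (A_hR = %.4f, A_hS = %.4f over q in [%.2f, %.2f], %d points)\n",
              x$abc, x$A_hR, x$A_hS, x$q_support[1], x$q_support[2], x$n_points))
  invisible(x)
}

#' Selectivity index rho = hR(S) / hR(R)
#'
#' Values well below 1 indicate strong differential selection between the
#' predicted-sensitive and relatively-resistant groups; rho near 1 indicates
#' no selectivity.
#'
#' @param hS,hR `group_comparison` objects for the S and R groups.
#' @return the ratio (possibly `Inf`), or `NA` if either input is undefined.
#' @export
selectivity_index <- function(hS, hR) {
  stopifnot(inherits(hS, "group_comparison"), inherits(hR, "group_comparison"))
  if (!hS$defined || !hR$defined) return(NA_real_)
  hS$hazard_ratio / hR$hazard_ratio
}
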