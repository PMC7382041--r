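# The treatment-by-covariate interaction Cox model and the differential
# log-hazard-ratio (dLHR) biomarker.
#
# The log hazard ratio relative to baseline is modeled as
#   xi(z, x) = beta0 * z + sum_l beta_l * x_l + z * sum_l gamma_l * x_l
# with z the binary treatment arm and x_l the K reduced covariates. The dLHR
#   dlhr(x) = xi(1, x) - xi(0, x) = beta0 + sum_l gamma_l * x_l
# is the log of a patient's experimental-to-control hazard ratio at fixed
# covariates; negative values favor the experimental arm. Direct effects
# beta_l cancel: only the interaction terms carry predictive information.

# Low-level Cox fit via the survival workhorse (Efron tie handling, no
# formula-parsing overhead; used thousands of times inside resampling loops).
.coxfit <- function(X, time, event, iter_max = 100, eps = 1e-9) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- survival::Surv(time, event)
  ctl <- survival::coxph.control(
    iter.max = iter_max, eps = eps,
    toler.chol = min(.Machine$double.eps^0.75, eps / 10))
  fit <- tryCatch(
    suppressWarnings(
      survival::coxph.fit(X, y, strata = NULL, offset = NULL,
                          init = rep(0, ncol(X)), control = ctl,
                          weights = NULL, method = "efron",
                          rownames = seq_len(nrow(X)))),
    error = function(e) NULL)
  if (is.null(fit) || is.character(fit)) return(NULL)
  # runaway coefficients signal separation (infinite MLE); treat as failure
  fit$converged <- !is.null(fit$iter) && fit$iter < iter_max &&
    !anyNA(fit$coefficients) && max(abs(fit$coefficients)) < 50
  fit
}

#' Fit the treatment-by-covariate interaction Cox model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the design
#' `[z, x_1..x_K, z*x_1..z*x_K]`. Covariate columns with zero variance are
#' excluded from the design and reported with coefficients exactly 0 (the
#' model collapses onto the remaining terms).
#'
#' @param covariates numeric matrix, samples x K, aligned with `clin` rows.
#' @param clin clinical table (see [validate_clinical()]).
#' @param iter_max,eps convergence control: iteration cap and relative
#'   log-partial-likelihood tolerance.
#' @return an object of class `cox_interaction_fit` with elements `beta0`,
#'   `beta`, `gamma` (length-K vectors), `covariance` ((2K+1) x (2K+1), ordered
#'   beta0, beta, gamma), `loglik`, `converged`, `n`, `n_events`, plus the
#'   covariate names.
#' @export
fit_interaction_cox <- function(covariates, clin, iter_max = 100, eps = 1e-9) {
  covariates <- as.matrix(covariates)
  validate_clinical(clin)
  if (nrow(covariates) != nrow(clin))
    stopf("covariates (%d rows) and clinical table (%d rows) differ",
          nrow(covariates), nrow(clin))
  K <- ncol(covariates)
  if (K < 1) stopf("need K >= 1 covariates")
  for (a in c(0, 1)) {
    if (!any(clin$event[clin$arm == a] == 1))
      stopf("arm %d has no observed events", a)
  }
  cn <- colnames(covariates) %||% paste0("x", seq_len(K))
  active <- apply(covariates, 2, stats::sd) > 0
  Xact <- covariates[, active, drop = FALSE]
  design <- cbind(z = clin$arm, Xact, clin$arm * Xact)
  # collinearity guard beyond the zero-variance drop
  if (qr(design)$rank < ncol(design))
    stopf("design matrix is rank deficient (collinear covariates)")
  fit <- .coxfit(design, clin$pfs_months, clin$event, iter_max, eps)
  if (is.null(fit)) stopf("Cox fit failed (degenerate or separated data)")
  if (anyNA(fit$coefficients))
    stopf("Cox fit produced undefined coefficients (collinear design)")
  ka <- sum(active)
  beta <- gamma <- numeric(K)
  beta[active] <- fit$coefficients[1 + seq_len(ka)]
  gamma[active] <- fit$coefficients[1 + ka + seq_len(ka)]
  covariance <- matrix(0, 2 * K + 1, 2 * K + 1)
  idx <- c(1, 1 + which(active), 1 + K + which(active))
  covariance[idx, idx] <- fit$var
  nm <- c("beta0", paste0("beta_", cn), paste0("gamma_", cn))
  dimnames(covariance) <- list(nm, nm)
  structure(list(
    beta0 = unname(fit$coefficients[1]),
    beta = stats::setNames(beta, cn),
    gamma = stats::setNames(gamma, cn),
    covariance = covariance,
    loglik = fit$loglik[length(fit$loglik)],
    converged = isTRUE(fit$converged),
    n = nrow(clin), n_events = sum(clin$event),
    covariate_names = cn,
    active = stats::setNames(active, cn)
  ), class = "cox_interaction_fit")
}

#' @export
print.cox_interaction_fit <- function(x, ...) {
  cat(sprintf("interaction Cox fit: K = %d, n = %d (%d events), %s\n",
              length(x$beta), x$n, x$n_events,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy_interaction_fit(x), row.names = FALSE)
  invisible(x)
}

#' Coefficient table for an interaction Cox fit
#'
#' One row per covariate with direct (beta) and interaction (gamma)
#' coefficients, Wald 95% confidence intervals and p-values, preceded by the
#' treatment-arm row (beta0).
#'
#' @param fit a `cox_interaction_fit`.
#' @param conf confidence level for the Wald intervals.
#' @return data.frame with columns component, beta, beta_lo, beta_hi, p_beta,
#'   gamma, gamma_lo, gamma_hi, p_gamma.
#' @export
tidy_interaction_fit <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "cox_interaction_fit"))
  K <- length(fit$beta)
  se <- sqrt(pmax(diag(fit$covariance), 0))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  est <- c(fit$beta0, fit$beta, fit$gamma)
  lo <- est - zq * se
  hi <- est + zq * se
  p <- 2 * stats::pnorm(-abs(ifelse(se > 0, est / se, 0)))
  p[se == 0] <- NA_real_
  data.frame(
    component = c("beta0", fit$covariate_names),
    beta = c(fit$beta0, unname(fit$beta)),
    beta_lo = lo[seq_len(K + 1)], beta_hi = hi[seq_len(K + 1)],
    p_beta = p[seq_len(K + 1)],
    gamma = c(NA_real_, unname(fit$gamma)),
    gamma_lo = c(NA_real_, lo[K + 1 + seq_len(K)]),
    gamma_hi = c(NA_real_, hi[K + 1 + seq_len(K)]),
    p_gamma = c(NA_real_, p[K + 1 + seq_len(K)]),
    stringsAsFactors = FALSE)
}

#' Differential log-hazard-ratio biomarker scores
#'
#' For each sample, `dlhr = beta0 + gamma . x`: the log of the experimental-
#' to-control hazard ratio predicted for that patient. Direct effects cancel
#' by construction.
#'
#' @param fit a converged `cox_interaction_fit`.
#' @param covariates samples x K matrix on the same covariates the model was
#'   fitted on; rownames, if present, become sample ids.
#' @return data.frame with columns `sample_id` and `dlhr` (one row per sample).
#' @export
dlhr <- function(fit, covariates) {
  stopifnot(inherits(fit, "cox_interaction_fit"))
  if (!fit$converged) stopf("refusing to score from a non-converged fit")
  covariates <- as.matrix(covariates)
  if (ncol(covariates) != length(fit$gamma))
    stopf("covariates have %d columns but the fit has K = %d",
          ncol(covariates), length(fit$gamma))
  scores <- as.numeric(fit$beta0 + covariates %*% fit$gamma)
  data.frame(sample_id = rownames(covariates) %||%
               as.character(seq_len(nrow(covariates))),
             dlhr = scores, stringsAsFactors = FALSE)
}

#' Classify the interaction scenario of a fitted model
#'
#' Diagnoses which qualitative regime a fit is in over a stated covariate
#' range: `no_interaction` when no interaction coefficient reaches Wald
#' significance; `strong` when the dLHR changes sign over the range (the
#' optimal arm flips between patients); `moderate` otherwise (all patients
#' favor the same arm, but to measurably different degrees).
#'
#' @param fit a `cox_interaction_fit`.
#' @param covariate_range numeric matrix K x 2 (per-component min, max), or a
#'   length-2 vector when K = 1.
#' @param alpha Wald significance level for the interaction terms.
#' @return one of "no_interaction", "moderate", "strong".
#' @export
classify_scenario <- function(fit, covariate_range, alpha = 0.05) {
  stopifnot(inherits(fit, "cox_interaction_fit"))
  K <- length(fit$gamma)
  rng <- matrix(covariate_range, ncol = 2)
  if (nrow(rng) != K) stopf("covariate_range must supply K = %d rows", K)
  gi <- K + 1 + seq_len(K)
  se <- sqrt(pmax(diag(fit$covariance)[gi], 0))
  pg <- ifelse(se > 0, 2 * stats::pnorm(-abs(fit$gamma / se)), 1)
  if (all(pg >= alpha)) return("no_interaction")
  lo <- fit$beta0 + sum(pmin(fit$gamma * rng[, 1], fit$gamma * rng[, 2]))
  hi <- fit$beta0 + sum(pmax(fit$gamma * rng[, 1], fit$gamma * rng[, 2]))
  if (lo < 0 && hi > 0) "strong" else "moderate"
}
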