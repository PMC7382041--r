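# Synthetic two-arm trial generator. Emulates the statistical structure the
# method assumes: standardized log2-scale expression with a low-dimensional
# latent signal, and survival times drawn from a proportional-hazards model
#   log(lambda/lambda0) = beta0*z + beta.w + z * gamma.w
# with independent exponential-plus-administrative censoring. The true dLHR
# (beta0 + gamma.w) is returned for oracle tests. Also builds the negative
# controls: random centroid sets and the single label permutation.

.gene_ids <- function(p) sprintf("g%05d", seq_len(p))
.sample_ids <- function(n) sprintf("s%04d", seq_len(n))

#' Configuration for a synthetic two-arm trial
#'
#' Defaults mirror a trial of the kind the method targets: n = 209 patients
#' randomized 1:2 to control:experimental (`arm_fraction = 2/3`), one latent
#' expression factor with a moderate-interaction hazard structure
#' (beta0 = -0.7, beta = -0.5, gamma = 1.0, so the experimental arm is favored
#' for most but not all of the latent range), an exponential baseline with
#' 0.12 events/month (median PFS about 6 months at covariates 0), light
#' independent censoring (0.03/month) and administrative censoring at 30
#' months.
#'
#' @param n number of patients.
#' @param p number of genes.
#' @param arm_fraction probability of assignment to the experimental arm.
#' @param K_latent number of latent expression factors.
#' @param beta0 treatment-arm coefficient.
#' @param beta,gamma direct and interaction coefficients (length K_latent).
#' @param baseline_rate exponential baseline hazard, events per month.
#' @param weibull_shape Weibull shape of the baseline (1 = exponential).
#' @param censor_rate independent exponential censoring rate per month.
#' @param admin_censor administrative censoring time, months.
#' @param n_informative genes loading on each latent factor (recycled to
#'   length K_latent; factors may drive blocks of different sizes).
#' @param loading loading strength of informative genes (recycled likewise).
#' @param noise_sd sd of gene-level gaussian noise.
#' @param subtype_centroids optional genes x centroids matrix; when supplied,
#'   expression on the centroid genes is generated as centroid mixtures whose
#'   mixing weights carry the latent signal (requires >= 2*K_latent centroids),
#'   so that centroid-correlation features can recover it.
#' @param subtype_strength latent-to-mixing-weight coupling in centroid mode.
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n = 209, p = 500, arm_fraction = 2/3,
                             K_latent = 1, beta0 = -0.7, beta = -0.5,
                             gamma = 1.0, baseline_rate = 0.12,
                             weibull_shape = 1, censor_rate = 0.03,
                             admin_censor = 30, n_informative = 20,
                             loading = 1, noise_sd = 1,
                             subtype_centroids = NULL, subtype_strength = 0.5,
                             seed = 1) {
  beta <- rep_len(beta, K_latent)
  gamma <- rep_len(gamma, K_latent)
  n_informative <- rep_len(as.integer(n_informative), K_latent)
  loading <- rep_len(loading, K_latent)
  if (n < 4 || p < 1) stopf("degenerate size: n = %d, p = %d", n, p)
  if (arm_fraction <= 0 || arm_fraction >= 1) stopf("arm_fraction must be in (0,1)")
  if (baseline_rate <= 0 || censor_rate <= 0 || admin_censor <= 0 ||
      weibull_shape <= 0)
    stopf("rates, shape and admin_censor must be positive")
  if (!is.null(subtype_centroids)) {
    validate_centroids(subtype_centroids)
    if (ncol(subtype_centroids) < 2 * K_latent)
      stopf("centroid mode needs >= 2*K_latent centroids")
  }
  structure(list(n = as.integer(n), p = as.integer(p),
                 arm_fraction = arm_fraction, K_latent = as.integer(K_latent),
                 beta0 = beta0, beta = beta, gamma = gamma,
                 baseline_rate = baseline_rate, weibull_shape = weibull_shape,
                 censor_rate = censor_rate, admin_censor = admin_censor,
                 n_informative = n_informative, loading = loading,
                 noise_sd = noise_sd, subtype_centroids = subtype_centroids,
                 subtype_strength = subtype_strength, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic two-arm trial
#'
#' @param config a [synthetic_config()].
#' @return list with `expr` (genes x samples matrix), `clin` (clinical table),
#'   `true_scores` (data.frame sample_id, dlhr = beta0 + gamma.w) and `latent`
#'   (n x K matrix of the generative covariates).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n; p <- cf$p; K <- cf$K_latent
    z <- stats::rbinom(n, 1, cf$arm_fraction)
    W <- matrix(stats::rnorm(n * K), n, K)
    if (is.null(cf$subtype_centroids)) {
      if (p < sum(cf$n_informative))
        stopf("p too small for %d informative genes", sum(cf$n_informative))
      X <- matrix(stats::rnorm(p * n, sd = cf$noise_sd), p, n)
      offset <- 0L
      for (l in seq_len(K)) {
        rows <- offset + seq_len(cf$n_informative[l])
        offset <- offset + cf$n_informative[l]
        X[rows, ] <- X[rows, ] +
          cf$loading[l] * matrix(W[, l], cf$n_informative[l], n, byrow = TRUE)
      }
      rownames(X) <- .gene_ids(p)
    } else {
      C <- cf$subtype_centroids
      J <- ncol(C); G <- nrow(C)
      A <- matrix(0, n, J)                       # centroid mixing weights
      for (l in seq_len(K)) {
        A[, 2 * l - 1] <- A[, 2 * l - 1] + cf$subtype_strength * W[, l]
        A[, 2 * l] <- A[, 2 * l] - cf$subtype_strength * W[, l]
      }
      Xc <- scale(C) %*% t(A) +
        matrix(stats::rnorm(G * n, sd = cf$noise_sd), G, n)
      extra <- max(cf$p - G, 0)
      Xn <- matrix(stats::rnorm(extra * n, sd = cf$noise_sd), extra, n)
      rownames(Xn) <- setdiff(.gene_ids(cf$p + G), rownames(C))[seq_len(extra)]
      X <- rbind(Xc, Xn)
      rownames(X)[seq_len(G)] <- rownames(C)
    }
    colnames(X) <- .sample_ids(n)
    xi <- cf$beta0 * z + as.numeric(W %*% cf$beta) + z * as.numeric(W %*% cf$gamma)
    u <- stats::runif(n)
    t_event <- (-log(u) / (cf$baseline_rate * exp(xi)))^(1 / cf$weibull_shape)
    t_cens <- pmin(stats::rexp(n, cf$censor_rate), cf$admin_censor)
    clin <- data.frame(sample_id = colnames(X), arm = z,
                       pfs_months = pmin(t_event, t_cens),
                       event = as.numeric(t_event <= t_cens),
                       stringsAsFactors = FALSE)
    true_scores <- data.frame(sample_id = colnames(X),
                              dlhr = cf$beta0 + as.numeric(W %*% cf$gamma),
                              stringsAsFactors = FALSE)
    list(expr = X, clin = clin, true_scores = true_scores, latent = W)
  })
}

#' Generate a random centroid set (negative control)
#'
#' Standard-normal centroid components on a random subset of a gene universe,
#' as used for a random-centroid control signature.
#'
#' @param p_genes size of the gene universe, or a character vector of gene ids
#'   to draw from.
#' @param n_centroids number of centroids.
#' @param n_genes number of genes the centroids are defined on.
#' @param seed integer seed.
#' @return genes x centroids numeric matrix.
#' @export
generate_random_centroids <- function(p_genes, n_centroids, n_genes, seed = 1) {
  universe <- if (is.character(p_genes)) p_genes else .gene_ids(p_genes)
  if (n_genes > length(universe)) stopf("n_genes exceeds the gene universe")
  with_seed(seed, {
    genes <- sort(sample(universe, n_genes))
    C <- matrix(stats::rnorm(n_genes * n_centroids), n_genes, n_centroids,
                dimnames = list(genes, paste0("RC", seq_len(n_centroids))))
    C
  })
}

#' Permute the expression-to-clinical linkage (negative control)
#'
#' Permutes the expression columns against the fixed clinical rows once,
#' breaking any correlation between expression and outcome while preserving
#' both marginals. Sample ids keep the clinical order, so downstream alignment
#' is unchanged.
#'
#' @param expr expression matrix aligned with `clin`.
#' @param clin clinical table.
#' @param seed integer seed (same seed, same permutation).
#' @return permuted expression matrix with the original column names.
#' @export
permute_labels <- function(expr, clin, seed = 1) {
  validate_expression(expr)
  if (!identical(colnames(expr), clin$sample_id))
    stopf("expression and clinical table not aligned")
  perm <- with_seed(seed, sample.int(ncol(expr)))
  out <- expr[, perm, drop = FALSE]
  colnames(out) <- colnames(expr)
  out
}
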