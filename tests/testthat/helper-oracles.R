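# Shared fixtures and independent oracles.

# Small clinical table builder.
mk_clin <- function(time, event, arm, ids = sprintf("s%03d", seq_along(time))) {
  data.frame(sample_id = ids, arm = arm, pfs_months = time, event = event,
             stringsAsFactors = FALSE)
}

# Expression matrix with generated dimnames.
mk_expr <- function(values, genes = NULL, samples = NULL) {
  x <- as.matrix(values)
  rownames(x) <- genes %||% sprintf("g%03d", seq_len(nrow(x)))
  colnames(x) <- samples %||% sprintf("s%03d", seq_len(ncol(x)))
  x
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent hand-written Cox log partial likelihood with Efron handling of
# tied event times (never calls the survival package).
oracle_cox_loglik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (tj in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == tj)
    R <- which(time >= tj)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D]) -
      sum(vapply(seq_len(d) - 1, function(l) log(sumR - (l / d) * sumD), 0))
  }
  ll
}

# Brute-force maximization of the oracle partial likelihood by iterated grid
# refinement (no gradients, no survival package). Final resolution ~5e-4.
oracle_cox_grid <- function(X, time, event, lim = 5, rounds = 8, pts = 11) {
  X <- as.matrix(X)
  K <- ncol(X)
  center <- rep(0, K)
  width <- lim
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(K), function(j)
      seq(center[j] - width, center[j] + width, length.out = pts))
    combo <- as.matrix(expand.grid(grids))
    ll <- apply(combo, 1, function(b) oracle_cox_loglik(b, X, time, event))
    center <- combo[which.max(ll), ]
    width <- width * 2 / (pts - 1) * 1.5   # keep the next window overlapping
  }
  center
}

# Numerical gradient of the oracle log partial likelihood.
oracle_cox_grad <- function(beta, X, time, event, h = 1e-6) {
  vapply(seq_along(beta), function(j) {
    e <- replace(rep(0, length(beta)), j, h)
    (oracle_cox_loglik(beta + e, X, time, event) -
       oracle_cox_loglik(beta - e, X, time, event)) / (2 * h)
  }, 0)
}

# Default small trial used across tests.
small_trial <- function(n = 160, gamma = 1.5, seed = 42, p = 60, ...) {
  generate_trial(synthetic_config(n = n, p = p, gamma = gamma, seed = seed,
                                  n_informative = 10, ...))
}
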