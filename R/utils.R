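# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so that
#' seeded package internals never disturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive B reproducible child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, B) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, B))
}

msg <- function(..., verbose = getOption("predsig.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
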