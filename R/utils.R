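#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates \code{expr}, and restores the previous RNG
#' state so that seeded package functions do not disturb the caller's
#' random stream.
#'
#' @param seed integer seed; \code{NULL} leaves the RNG untouched.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a base seed
#'
#' Deterministic splitting of one user-facing seed into per-stage seeds,
#' kept below 2^31 so the result is always a valid R integer.
#'
#' @param seed base integer seed.
#' @param k stage index (>= 1).
#' @return integer seed.
#' @keywords internal
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

upper_vals <- function(m) m[upper.tri(m)]

#' Symmetric matrix from upper-triangle values
#' @keywords internal
#' @noRd
sym_from_upper <- function(vals, k, diag_val = 0) {
  m <- matrix(diag_val, k, k)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_val
  m
}
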