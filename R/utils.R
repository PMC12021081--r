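#' @keywords internal
"_PACKAGE"

# Numerical floor used before any log(); see the methods vignette.
.EPS <- 1e-8

#' Row-wise softmax
#'
#' Numerically stable softmax over the rows of a matrix of logits.
#'
#' @param logits numeric matrix (cells x classes).
#' @return matrix of the same shape with non-negative rows summing to 1.
#' @keywords internal
row_softmax <- function(logits) {
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

clip_prob <- function(p, eps = .EPS) {
  pmin(pmax(p, eps), 1 - eps)
}

# xlogx with the 0 * log 0 == 0 convention (natural log throughout).
xlogx <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log(p[pos])
  out
}

# add a row vector b to every row of matrix X without forming a full matrix of b
add_bias <- function(X, b) {
  sweep(X, 2L, b, "+")
}

#' Derive a stream-specific 32-bit seed from a base seed
#'
#' Keeps derived seeds inside the signed 32-bit range expected by
#' \code{set.seed}.
#'
#' @param seed integer base seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) * 48271 + stream * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
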