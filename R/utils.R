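## Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Each random
#' component draws from its own stream, obtained by an affine map of the root
#' seed and a small stream index, reduced modulo 2^31 - 1. Streams are stable
#' across sessions and independent of the global RNG state.
#'
#' @param seed integer root seed.
#' @param stream small non-negative integer identifying the consumer.
#' @return an integer seed usable with [set.seed()].
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stream))
  as.integer((abs(as.double(seed)) * 1000003 + as.double(stream)) %% 2147483647)
}

## Run expr under a seed without disturbing the caller's RNG state.
with_stream <- function(seed, stream, expr) {
  withr::with_seed(stream_seed(seed, stream), expr)
}

## Rescale to [0, 1]; constant input maps to 0.5 (midpoint convention).
unit01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1]) / diff(rng)
}

## Canonical key for an unordered site pair.
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}
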