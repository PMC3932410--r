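# Seed derivation and scoped RNG.
#
# Every stochastic component (spatial sampling, orientation offsets, encoding
# noise, truth assignment, decision tie-breaks) draws from its own stream,
# derived deterministically from a single master seed so that components can
# be varied independently without perturbing one another.

# Purpose identifiers for derived streams.
.STREAMS <- c(sampling = 1L, orientation = 2L, noise = 3L, truth = 4L, decision = 5L)

#' Derive a child seed from a parent seed and integer tags
#'
#' Deterministic multiplicative-congruential mixing (Lehmer constants, modulus
#' 2^31 - 1) of a parent seed with one or more integer tags. Used internally to
#' give every trial and every noise source its own reproducible stream.
#'
#' @param seed Parent seed (non-negative integer-valued scalar).
#' @param ... Further integer tags (e.g. condition index, trial index,
#'   stream id), mixed in order.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(42, 3, 1)
#' @export
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  m <- 2147483647
  h <- 17
  for (k in tags) {
    k <- abs(as.numeric(k)) %% m
    h <- (h * 48271 + k + 11) %% m
    h <- (h * 48271 + 7919) %% m
  }
  as.integer(h)
}

# Evaluate expr with a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Named stream seeds for one logical unit of work (a trial or a batch).
stream_seeds <- function(seed) {
  vapply(.STREAMS, function(id) derive_seed(seed, 990000L + id), integer(1))
}
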