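## Named, reproducible RNG streams.
##
## Every source of randomness in the package flows from one root seed that is
## split into independent named streams (data generation, weight init, mask
## draws, shuffling, baselines).  A draw is addressed by (stream, index), so a
## Monte Carlo run of T passes can be continued: passes a+1, ..., a+b of a
## longer run reuse the same per-pass seeds as a fresh run started at offset a.

#' Derive a child seed from a stream identifier and a draw index
#'
#' Mixes a stream id and a draw index into a single seed in `[0, 2^31)`.
#' The map is deterministic, so the same `(stream, index)` pair always yields
#' the same seed, and distinct pairs collide with negligible probability.
#'
#' @param stream Integer-like stream identifier (may itself be a mixed seed).
#' @param index Nonnegative integer draw index within the stream.
#' @return A single integer seed.
#' @export
mix_seed <- function(stream, index = 0L) {
  stopifnot(is.numeric(stream), length(stream) == 1L,
            is.numeric(index), length(index) == 1L)
  m <- 2147483629 # largest prime below 2^31
  s <- (abs(stream) %% m)
  # two rounds of a multiplicative-congruential mix keep streams apart even
  # for adjacent (stream, index) pairs
  s <- (s * 48271 + (abs(index) %% m)) %% m
  s <- (s * 16807 + 12345) %% m
  as.integer(s)
}

#' Derive the seed for a named stream under a root seed
#'
#' @param root_seed Root seed of the run.
#' @param stream_name Character name ("data", "init", "masks", "shuffle", ...).
#' @return An integer seed for the named stream.
#' @export
seed_stream <- function(root_seed, stream_name) {
  h <- sum(utf8ToInt(stream_name) * seq_along(utf8ToInt(stream_name)) * 131)
  mix_seed(root_seed, h)
}

## Evaluate `expr` under a given seed without disturbing the caller's RNG
## state (the global .Random.seed is saved and restored).
with_local_seed <- function(seed, expr) {
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
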