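# Reproducibility plumbing. Every public entry point that consumes
# randomness takes a single integer seed; internal stages derive child
# seeds from (seed, counter) so each stage is reproducible in isolation
# and adding a stage never reshuffles the streams of the others.

#' Derive a child seed from a parent seed and a counter
#'
#' Deterministic integer hash used internally to hand independent RNG
#' streams to sub-stages (expression noise, survival noise, CV repeats,
#' per-fold training, per-method sampling). Exposed because reproducing a
#' single stage of a larger run requires the same derivation.
#'
#' @param seed parent integer seed.
#' @param index non-negative integer counter identifying the sub-stage.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, index) {
  s <- (abs(as.double(seed)) %% 2147483647)
  x <- (s * 48271 + (as.double(index) + 1) * 1299721) %% 2147483647
  as.integer(x)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# sprintf-based numeric formatting that survives a text round trip exactly
# (17 significant digits round-trips IEEE doubles).
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}
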