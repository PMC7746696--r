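#' Derive a reproducible sub-stream seed
#'
#' Every source of randomness in the pipeline draws its seed from the run
#' seed through a named sub-stream (selection, crossover, mutation, shuffle,
#' ...), so stages can be re-run independently yet bit-identically. The
#' derivation is a small multiplicative string hash folded into the Mersenne
#' prime 2^31 - 1; it is stable across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param label character sub-stream name.
#' @param index optional integer for per-item streams (cycle number, pair
#'   index, ...).
#' @return a single integer in \[1, 2^31 - 2\], usable with [set.seed()].
#' @export
#' @examples
#' deriveSeed(17, "crossover", 3)
deriveSeed <- function(seed, label, index = 0L) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(label)) h <- (h * 69069 + b) %% m
  h <- (h * 69069 + as.numeric(index) %% m) %% m
  as.integer(h %% (m - 2) + 1)
}

# run expr with a local, seeded RNG without touching the caller's RNG state
withSeed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
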