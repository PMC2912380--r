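#' Derive a reproducible child seed from a master seed and a stage tag
#'
#' A single master seed is expanded into per-stage seeds so that every stage
#' of a simulation (marker map, haplotype pool, cohort sampling, phenocopy
#' injection, cross-validation folds, ...) is independently reproducible.
#' The derivation is a small multiplicative hash over the tag characters,
#' reduced modulo 2^31 - 1 so the result is always a valid R integer seed.
#'
#' @param seed master integer seed
#' @param tag character scalar naming the stage (e.g. `"pool"`, `"cc/ME/0.05"`)
#' @return an integer seed in `[1, 2^31 - 2]`, deterministic in `(seed, tag)`
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag), length(tag) == 1L)
  m <- 2147483647
  s <- as.double(seed %% m)
  for (c in utf8ToInt(tag)) {
    s <- (s * 31 + c) %% m
  }
  as.integer(s %% (m - 2L) + 1L)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
local_rng <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
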