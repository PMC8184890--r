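#' Derive a named substream seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its randomness from a
#' substream derived from one global integer seed and a stage name, so
#' stages are reproducible in isolation and adding a stage never perturbs
#' the draws of another.
#'
#' @param seed global integer seed.
#' @param stream character stage name, e.g. `"haplotypes"`.
#' @return an integer seed (always below 2^31) for `set.seed()`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  ## cheap string hash (djb2) folded with the global seed
  h <- 5381
  for (ch in utf8ToInt(stream)) h <- (h * 33 + ch) %% 2147483647
  as.integer((abs(as.integer(seed)) %% 2147483647 * 7919 + h) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
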