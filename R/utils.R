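#' Derive a reproducible integer seed for a named substream
#'
#' All randomness in a run flows from one top-level seed; per-gene (or
#' per-replicate) streams are derived from `(seed, key)` so results do not
#' depend on the order in which genes are processed.
#'
#' @param seed integer master seed.
#' @param key character key naming the substream (e.g. a gene id).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' stream_seed(1, "Sox2")
stream_seed <- function(seed, key) {
  h <- as.double(as.integer(seed)) %% 2147483647
  for (c in utf8ToInt(as.character(key))) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
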