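`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific sub-seed from a global seed
#'
#' Deterministic, stage-name-keyed derivation so pipeline stages can be rerun
#' in isolation under one global seed. Result is a positive 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Stage name (string).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 48271 + h * 7919) %% 2147483629)
}
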