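#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package fans out from a single master seed through
#' named sub-seeds, so each stage (design, reaction times, each session's
#' noise, classifier initialisation, evaluation splits, ...) is independently
#' reproducible. The derivation hashes the label with a small multiplicative
#' scheme and folds it into the master seed; the result always fits a 32-bit
#' signed integer.
#'
#' @param seed master seed (non-negative integer).
#' @param label character label naming the stage, e.g. `"brt/C_o"` or
#'   `"session/3/eeg"`.
#' @return an integer seed in `[0, 2^31 - 1]`.
#' @export
#' @examples
#' derive_seed(1, "design") != derive_seed(1, "brt")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  h <- 0
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((seed + h * 2654435) %% 2147483647)
}
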