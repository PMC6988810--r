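`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from the master seed
#'
#' Deterministic linear-congruential mix keeping every derived seed in
#' the 32-bit signed range, so one master seed reproducibly governs
#' every randomized stage.
#'
#' @param master integer master seed.
#' @param stage integer stage index (or a stage name, hashed by
#'   character codes).
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  if (is.character(stage))
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + as.numeric(stage) * 1000003) %%
               2147483647)
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}
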