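#' Derive a stage seed from a master seed
#'
#' Deterministic splitting rule so every pipeline stage can be reproduced in
#' isolation: the stage name is folded into the master seed with a 31-base
#' polynomial hash modulo 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  mod <- 2147483647
  s <- as.numeric(master) %% mod
  for (c in utf8ToInt(stage)) {
    s <- (s * 31 + c) %% mod
  }
  as.integer(s %% (mod - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
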