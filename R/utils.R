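# Internal helpers: seeded evaluation and per-stage seed derivation.

# Evaluate expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' Pipeline stages draw their own seeds from the master seed and the stage
#' name, so any stage can be re-run in isolation with reproducible results.
#' The derivation is a fixed integer hash, kept within 32-bit range.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"simulate"`, `"boruta_all"`).
#' @return a single integer seed.
#' @export
stageSeed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1048573
  as.integer((abs(master) %% 65521) * 32749 + h) %% 2147483647L
}

# Internal: named numeric -> one-row data.frame
.fv_to_row <- function(fv) {
  as.data.frame(as.list(fv), check.names = FALSE)
}
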