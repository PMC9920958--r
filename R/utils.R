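# RNG discipline: every stochastic entry point takes a seed, sets it inside
# a restore-on-exit guard so package calls never disturb the caller's RNG.

local_rng <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}

#' Derive a stage seed from a global seed
#'
#' One run seed fans out to per-stage seeds through a fixed integer-hash
#' derivation, so any stage can be re-run in isolation with the same
#' stream. Results stay inside the 32-bit integer range.
#'
#' @param seed global integer seed.
#' @param stage stage name (string) or index.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  val <- (as.double(seed) * 69069 + as.double(stage) * 2654435761) %% 2147483647
  as.integer(val)
}
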