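#' Derive a reproducible sub-seed from a master seed
#'
#' All stochastic stages draw their randomness from one master seed; per-unit
#' substreams (per subject, per CV repetition, per SFS inner loop) use seeds
#' derived deterministically from the master seed and small integer indices.
#' The derivation is a multiplicative-congruential mix kept strictly below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed master seed (integer).
#' @param ... one or more non-negative integer indices identifying the
#'   substream (e.g. subject index, repetition index).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 16807 + 12345) %% m
  }
  as.integer(s)
}

#' Evaluate an expression with a temporarily fixed RNG state
#'
#' Saves and restores `.Random.seed` around `expr`, so seeded internals do not
#' perturb the caller's random stream.
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
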