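# internal helpers: classed errors, scoped RNG, seed derivation

fa_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "fitassay_error")))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index, kept inside
#' 32-bit integer range. Used so that one master seed drives every random
#' component of a simulation or pipeline run independently.
#'
#' @param seed master seed (integer-like).
#' @param k stream index (integer-like).
#' @return an integer seed.
#' @export
child_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147483647) * 48271
  s <- s %% 2147483647
  as.integer((s + 104729 * (abs(as.numeric(k)) %% 20011)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
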