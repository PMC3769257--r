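# Internal RNG helpers.
#
# All stochastic exported functions take an optional `seed`; when supplied the
# draw happens in a local RNG scope so the caller's random stream is left
# untouched.

run_with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seeds derived from one master seed: used by the
# study engine so each (scenario, risk, replicate) cell is independently
# reproducible regardless of evaluation order.
derive_seeds <- function(master_seed, n) {
  run_with_seed(master_seed, sample.int(.Machine$integer.max, n, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
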