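# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
  }
  force(expr)
}

# round() in R rounds half to even; library construction specifies
# round-half-up so that GC counts are reproducible integers.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)
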