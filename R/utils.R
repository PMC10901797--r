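# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched, so generation/splitting is deterministic given `seed` regardless
# of surrounding RNG use.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_ <- function(...) stop(..., call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
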