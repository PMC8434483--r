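# internal helpers shared across modules

# round-half-up, the only rounding convention consistent with both published
# split sizes (159 -> 127 modeling, 127 -> 102 training)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gg <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_gg(sprintf("`%s` must be a single finite number", name))
  }
}

# deterministic per-task RNG scoping: runs `expr` under `seed` and restores
# the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
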