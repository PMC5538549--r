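`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' All generators in the package funnel their randomness through this helper:
#' the global RNG state is saved, the requested seed installed, and the prior
#' state restored on exit, so seeded generators never perturb a caller's RNG
#' stream.
#'
#' @param seed single integer seed (required; no hidden global state).
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed))
    stop("a single finite integer 'seed' is required")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## round-half-up, used for printed kb interval sizes (base round() is
## round-half-even, which would not match hand arithmetic on .5 boundaries)
round_half_up <- function(x) floor(x + 0.5)

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", what, "' must be a single finite number")
  invisible(x)
}
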