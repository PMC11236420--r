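#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under a local Mersenne-Twister stream seeded with `seed`,
#' restoring the caller's RNG state afterwards so that seeded generators never
#' disturb the global stream.
#'
#' @param seed Integer seed (must fit in a 32-bit integer).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (abs(seed) >= 2^31) abort("`seed` must fit in a 32-bit integer.")
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed; keeps results < 2^31 and distinct
# across `offset` so independent stages of a pipeline get independent streams.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2017L + as.integer(offset)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                closed_lower = TRUE, closed_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok_low <- if (closed_lower) x >= lower else x > lower
  ok_up <- if (closed_upper) x <= upper else x < upper
  if (!ok_low || !ok_up) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s.", name,
      if (closed_lower) "[" else "(", format(lower), format(upper),
      if (closed_upper) "]" else ")"
    ))
  }
  invisible(x)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
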