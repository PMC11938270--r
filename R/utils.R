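`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
stop_input <- function(..., call. = FALSE) stop(..., call. = call.)

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
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

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE, strict_max = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) && !is.infinite(x)) {
    stop_input(sprintf("'%s' must be a single number", name))
  }
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  if (!lo_ok || !hi_ok) {
    stop_input(sprintf(
      "'%s' must be in %s%s, %s%s (got %s)", name,
      if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]", format(x)
    ))
  }
  invisible(x)
}
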