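#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' package functions never disturb the global random stream.
#' @noRd
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_protac <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_protac(sprintf("'%s' must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_protac(sprintf("'%s' must be a single finite number", name))
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_protac(sprintf(
      "'%s' must lie in %s%g, %g%s (got %g)", name,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_fraction_vec <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_protac(sprintf("'%s' must contain fractions in [0, 1]", name))
  }
  invisible(x)
}

## Stable smaller root of x^2 - b*x + c = 0 (b > 0, c >= 0, b^2 >= 4c):
## written as 2c / (b + sqrt(b^2 - 4c)) to avoid catastrophic cancellation.
smaller_quad_root <- function(b, c) {
  disc <- b^2 - 4 * c
  disc[disc < 0 & disc > -1e-12 * b^2] <- 0
  2 * c / (b + sqrt(disc))
}
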