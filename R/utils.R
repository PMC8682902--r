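#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so seeded generators do not disturb
#' the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# scalar validation helpers -------------------------------------------------

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("`%s` = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

check_increasing <- function(x, name) {
  if (length(x) < 1L || anyNA(x) || any(diff(x) <= 0))
    stop(sprintf("`%s` must be strictly increasing with no missing values",
                 name), call. = FALSE)
  invisible(x)
}

#' Trapezoidal integral of uniformly sampled values
#' @param y sampled values.
#' @param dx sample spacing.
#' @keywords internal
#' @noRd
trapz_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}
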