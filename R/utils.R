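# Internal helpers: argument checks and reproducible sub-stream seeding.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x)) {
    stopf("`%s` must be numeric and non-missing", name)
  }
  if (any(x < lower) || any(x > upper)) {
    stopf("`%s` must lie in [%s, %s]", name, format(lower), format(upper))
  }
  invisible(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `expr`,
#' and restores the previous state on exit. All randomness in the package
#' flows through this helper so a single named seed reproduces every run.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed for session/neuron i under a parent seed.
# Linear-congruential step keeps results inside 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

clip01 <- function(x) pmin(1, pmax(0, x))

# Arcsine variance-stabilizing transform for proportions; exported as a
# utility for external ANOVA-style testing, never used inside model fits.

#' Arcsine square-root transform for proportions
#'
#' @param p proportions in `[0, 1]`.
#' @return `asin(sqrt(p))` in radians.
#' @export
arcsine_transform <- function(p) {
  check_number(p, "p", 0, 1)
  asin(sqrt(p))
}
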