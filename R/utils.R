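# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("`%s` must be a single finite number", name)
  ok <- if (strict) x > lower else x >= lower
  if (!ok) stopf("`%s` must be %s %s", name, if (strict) ">" else ">=", lower)
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is untouched. All stochastic package functions that take
# an explicit `seed` route through here, which is what makes whole-pipeline
# runs byte-reproducible.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds below 2^31, so nested stages can be reseeded
# independently of evaluation order.
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

# Linear interpolation of a series onto new times, constant extrapolation.
interp_series <- function(t_from, v, t_to) {
  approx(t_from, v, xout = t_to, rule = 2)$y
}
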