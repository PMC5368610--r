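# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; if `seed`
# is NULL, use the ambient RNG stream (and advance it). Restores the caller's
# .Random.seed only when a seed was supplied, so seeded calls do not disturb
# an enclosing seeded computation.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Truncated normal draw by resampling (used for strictly positive clinical
# quantities like disease duration).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

# Column-standardize a matrix; zero-variance columns become all-zero
# instead of NaN (relevant for constant edge features).
safe_scale <- function(x) {
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  s[s < .Machine$double.eps] <- Inf
  sweep(sweep(x, 2, mu), 2, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
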