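# Internal helpers.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is untouched. seed = NULL means "use the current
# stream" (still restoring nothing).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Clopper-Pearson exact CI for x successes in n trials, on the proportion
# scale.
.clopperPearson <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  alpha <- 1 - level
  low <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(low = low, high = high)
}

# Derive a stream of sub-seeds from one master seed, staying within the
# 32-bit integer range.
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max, n))
}
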