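# Internal numerical helpers shared across modules.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Deterministic substream derivation: mixes a master seed with small integer
# tags into a new seed below 2^31. Arithmetic kept within double precision
# (all intermediates < 2^53).
.deriveSeed <- function(seed, ...) {
  tags <- c(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (t in tags) {
    h <- (h * 48271 + (as.numeric(t) %% 2147483647) * 16807 + 11) %% 2147483647
  }
  as.integer(h)
}

# Run an expression under a local RNG state so callers' RNG is untouched.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Separable Gaussian smoothing of a matrix-shaped random field.
.smoothField <- function(z, sd = 2) {
  k <- function(n) {
    d <- outer(seq_len(n), seq_len(n), function(i, j) (i - j)^2)
    m <- exp(-d / (2 * sd^2))
    m / rowSums(m)
  }
  k(nrow(z)) %*% z %*% t(k(ncol(z)))
}

.assertCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1L)
    stop(sprintf("'%s' must be a single count >= 1", what), call. = FALSE)
  as.integer(x)
}
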