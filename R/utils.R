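# Internal helpers shared across modules.

# Evaluate expr under a local RNG state seeded with `seed`; the caller's RNG
# stream is left untouched. A NULL seed uses (and advances) the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with window of `n` samples (n >= 1); edges use the
# partial window so the output length matches the input.
movingAverage <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  kern <- rep(1, n)
  num <- stats::filter(x, kern, sides = 2)
  den <- stats::filter(rep(1, length(x)), kern, sides = 2)
  out <- as.numeric(num / den)
  # stats::filter leaves NAs at the edges for even/odd windows; fill them with
  # partial-window means.
  bad <- which(is.na(out))
  half <- n %/% 2
  for (i in bad) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# First/second numerical derivative on a uniform grid (central differences,
# one-sided at the edges).
numDeriv1 <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

numDeriv2 <- function(x, dt) {
  n <- length(x)
  if (n < 3) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) / dt^2
  d
}

# Largest-remainder apportionment of `n` units to fractions summing to 1.
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Histogram counts of x on strictly increasing bin edges; values on the far
# right edge fall into the last bin, values outside the edges are dropped.
binCount <- function(x, edges) {
  x <- x[x >= edges[1] & x <= edges[length(edges)]]
  if (!length(x)) return(rep(0L, length(edges) - 1L))
  tabulate(findInterval(x, edges, rightmost.closed = TRUE),
           nbins = length(edges) - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
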