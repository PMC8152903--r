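# Internal helpers shared across modules.

# Derive n reproducible child seeds from one master seed. Uses R's own RNG in
# a local scope so the caller's RNG state is untouched; keeps seeds < 2^31.
deriveSeeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run expr with a given seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# All permutations of 1..n as a matrix (n! rows); recursion is fine for n <= 8.
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- seq_len(nrow(sub)) + r
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

# Polynomial rolling hash of a character scalar, returned as 8 hex digits.
# Used only to stamp outputs with a config fingerprint for provenance.
configHash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

# Centered moving average with symmetric window shrinkage at the edges.
runningMean <- function(x, nPoints) {
  n <- length(x)
  if (nPoints == 1L || n == 1L) return(x)
  half <- (nPoints - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  h <- pmin(half, idx - 1L, n - idx)
  (cs[idx + h + 1L] - cs[idx - h]) / (2 * h + 1)
}
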