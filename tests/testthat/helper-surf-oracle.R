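# Independent brute-force SURF reference: plain quadratic loops, one
# feature at a time, no shared code with surfRank(). Used as the oracle in
# the equivalence tests.

surfBruteForce <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  lo <- apply(X, 2, min)
  rng <- apply(X, 2, max) - lo
  rng[rng < 1e-12] <- 1
  Xs <- X
  for (f in seq_len(p)) Xs[, f] <- (X[, f] - lo[f]) / rng[f]

  d <- function(i, j) sqrt(sum((Xs[i, ] - Xs[j, ])^2))
  dsum <- 0; npair <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dsum <- dsum + d(i, j); npair <- npair + 1
  }
  thr <- dsum / npair

  W <- numeric(p)
  for (i in seq_len(n)) {
    hits <- c(); miss <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      if (d(i, j) < thr) {
        if (y[j] == y[i]) hits <- c(hits, j) else miss <- c(miss, j)
      }
    }
    for (f in seq_len(p)) {
      for (j in miss) W[f] <- W[f] + abs(Xs[i, f] - Xs[j, f]) / (n * length(miss))
      for (j in hits) W[f] <- W[f] - abs(Xs[i, f] - Xs[j, f]) / (n * length(hits))
    }
  }
  W
}

randomSampleSet <- function(seed, maxN = 20L, maxP = 6L) {
  set.seed(seed)
  n <- sample(6:maxN, 1)
  p <- sample(2:maxP, 1)
  y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))  # both classes present
  X <- matrix(stats::rnorm(n * p, mean = y, sd = 1.5), n, p)
  list(X = X, y = y)
}
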