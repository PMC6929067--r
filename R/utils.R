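# Small internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 5-bin histogram of intensities over fixed absolute bins of [0, 1],
# normalized to sum 1. Values at 1 fall in the last bin.
hist5 <- function(v) {
  b <- pmin(floor(v * 5), 4)
  tabulate(b + 1L, 5L) / length(v)
}

# Shannon entropy (bits) of a probability vector; 0 log 0 := 0.
shannonEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Moment statistics that stay finite on constant inputs: skewness and
# (excess) kurtosis are defined as 0 when the standard deviation vanishes.
safeSkewness <- function(v) {
  if (stats::sd(v) < 1e-12) return(0)
  e1071::skewness(v, type = 3)
}

safeKurtosis <- function(v) {
  if (stats::sd(v) < 1e-12) return(0)
  e1071::kurtosis(v, type = 3)
}

# Replicate-pad a matrix by `k` pixels on every side.
padReplicate <- function(m, k) {
  if (k <= 0L) return(m)
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

# Zero-pad a matrix by `k` pixels on every side.
padZero <- function(m, k) {
  if (k <= 0L) return(m)
  out <- matrix(0, nrow(m) + 2L * k, ncol(m) + 2L * k)
  out[(k + 1L):(k + nrow(m)), (k + 1L):(k + ncol(m))] <- m
  out
}

# 2D convolution with replicate boundary via EBImage; pads the image when
# the kernel would exceed the image size (EBImage::filter2 requires
# kernel <= image).
convolve2 <- function(m, kern) {
  kr <- (dim(kern) - 1L) %/% 2L
  pad <- max(0L, max(max(dim(kern)) - min(dim(m)), max(kr)))
  mp <- padReplicate(m, pad)
  out <- EBImage::filter2(mp, kern, boundary = "replicate")
  if (pad > 0L)
    out <- out[(pad + 1L):(pad + nrow(m)), (pad + 1L):(pad + ncol(m)), drop = FALSE]
  out
}

# Odd-sized normalized Gaussian kernel, capped so it never exceeds the
# image dimension it will be applied to.
gaussianKernel <- function(sigma, maxSide = Inf) {
  h <- max(1L, ceiling(3 * sigma))
  if (is.finite(maxSide)) h <- min(h, max(1L, (as.integer(maxSide) - 1L) %/% 2L))
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Central-difference gradients with replicate borders.
gradientY <- function(m) {
  up <- m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
  (dn - up) / 2
}

gradientX <- function(m) {
  lf <- m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE]
  (rt - lf) / 2
}

# Coerce an ERMMap-or-binary-matrix argument to a plain binary matrix.
asMapMatrix <- function(x) {
  if (is(x, "ERMMap")) return(x@grid)
  if (is.matrix(x)) {
    if (!all(x %in% c(0, 1))) stop("map matrix must be binary (0/1)")
    return(x)
  }
  stop("expected an ERMMap or a binary matrix")
}
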