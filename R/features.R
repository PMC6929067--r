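# 452-feature characterization of ILM points.
#
# Each ILM point is described by a vertical rectangular window of width
# subSide and height 5*subSide, centered laterally on the point and
# vertically on the ILM row, composed of five stacked square sub-windows
# (sub-windows 1-2 sample the vitreous/ERM space above the surface, 3
# straddles it, 4-5 sample the retina below). Heavy filter responses
# (Gabor, Laws, LBP codes, gradients) are computed once per B-scan and the
# per-point features are cheap window aggregations of those maps.

#' Window geometry for feature extraction
#'
#' @param subSide side length (px) of each square sub-window; odd, >= 5.
#'   The full window is \code{subSide} wide and \code{5 * subSide} tall.
#' @return named list with the derived half-extents.
#' @export
windowGeometry <- function(subSide = 15L) {
  subSide <- as.integer(subSide)
  stopifnot(subSide >= 5L, subSide %% 2L == 1L)
  list(subSide = subSide, nSub = 5L,
       halfW = (subSide - 1L) %/% 2L,
       winH = 5L * subSide,
       halfH = (5L * subSide - 1L) %/% 2L)
}

GABOR_WAVELENGTHS <- c(2, 3, 5, 8)
GABOR_ORIENTATIONS <- (0:7) * pi / 8
LAWS_VECTORS <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
                     S5 = c(-1, 0, 2, 0, -1), W5 = c(-1, 2, 0, -2, 1),
                     R5 = c(1, -4, 6, -4, 1))
# 14 Laws energy maps: the 4 non-trivial diagonal masks plus the 10
# symmetric off-diagonal pairs (L5L5, a pure local mean, is dropped).
LAWS_PAIRS <- list(
  c("E5", "E5"), c("S5", "S5"), c("W5", "W5"), c("R5", "R5"),
  c("L5", "E5"), c("L5", "S5"), c("L5", "W5"), c("L5", "R5"),
  c("E5", "S5"), c("E5", "W5"), c("E5", "R5"),
  c("S5", "W5"), c("S5", "R5"), c("W5", "R5"))

WINDOW_STAT_NAMES <- c("mean", "sd", "min", "max", "median", "range",
                       "skewness", "kurtosis", "entropy", "energy",
                       paste0("hist", 1:5))
GLOBAL_STAT_NAMES <- c("mean", "median", "sd", "variance", "min", "max",
                       "range", "skewness", "kurtosis", "entropy", "energy",
                       "p25", "p75")

# The fixed per-category composition of the 452-value descriptor.
featureCounts <- function() {
  c(pca = 10L, glcm = 16L, gabor = 160L, lbp = 64L, laws = 28L,
    window = 75L, global = 13L, glih = 5L, hog = 81L)
}

buildRegistry <- function() {
  glcmProps <- c("contrast", "correlation", "energy", "homogeneity")
  glcmDirs <- c("d000", "d045", "d090", "d135")
  lawsNames <- vapply(LAWS_PAIRS, paste, character(1L), collapse = "")
  nm <- c(
    sprintf("pca_%02d", 1:10),
    paste("glcm", rep(glcmProps, each = 4L), glcmDirs, sep = "_"),
    sprintf("gabor_w%g_o%d_s%d",
            rep(GABOR_WAVELENGTHS, each = 40L),
            rep(rep(0:7, each = 5L), times = 4L),
            rep(1:5, times = 32L)),
    sprintf("lbp_%02d", 0:63),
    paste("laws", rep(lawsNames, each = 2L), c("mean", "sd"), sep = "_"),
    sprintf("win_s%d_%s", rep(1:5, each = 15L), rep(WINDOW_STAT_NAMES, 5L)),
    paste0("glob_", GLOBAL_STAT_NAMES),
    sprintf("glih_%d", 1:5),
    sprintf("hog_c%d_b%d", rep(1:9, each = 9L), rep(1:9, 9L)))
  cnt <- featureCounts()
  cat <- factor(rep(names(cnt), cnt), levels = names(cnt))
  stopifnot(sum(cnt) == 452L, length(nm) == 452L, !anyDuplicated(nm))
  list(names = nm, categories = cat)
}

.registry <- NULL
getRegistry <- function() {
  if (is.null(.registry)) {
    reg <- buildRegistry()
    utils::assignInMyNamespace(".registry", reg)
  }
  .registry
}

#' Canonical names and categories of the 452 features
#'
#' Feature order is fixed: PCA (10), GLCM (16), Gabor (160), LBP (64),
#' Laws (28), window (75), intensity-global (13), GLIH (5), HOG (81).
#'
#' @return \code{featureNames()}: character vector of length 452.
#'   \code{featureCategories()}: aligned factor of category labels.
#' @export
featureNames <- function() getRegistry()$names

#' @rdname featureNames
#' @export
featureCategories <- function() getRegistry()$categories

# ---- filter banks -------------------------------------------------------

gaborKernel <- function(wavelength, theta, psi, sigma = 0.56 * wavelength,
                        aspect = 0.5) {
  h <- max(2L, ceiling(2.5 * sigma))
  g <- expand.grid(y = -h:h, x = -h:h)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  k <- exp(-(xr^2 + aspect^2 * yr^2) / (2 * sigma^2)) *
    cos(2 * pi * xr / wavelength + psi)
  matrix(k, 2L * h + 1L, 2L * h + 1L)
}

gaborBank <- function() {
  bank <- list()
  i <- 0L
  for (w in GABOR_WAVELENGTHS) for (th in GABOR_ORIENTATIONS) {
    i <- i + 1L
    re <- gaborKernel(w, th, 0)
    re <- re - mean(re)                      # DC-free: zero on constants
    im <- gaborKernel(w, th, pi / 2)
    bank[[i]] <- list(re = re, im = im)
  }
  bank
}

.gaborBankCache <- NULL
getGaborBank <- function() {
  if (is.null(.gaborBankCache))
    utils::assignInMyNamespace(".gaborBankCache", gaborBank())
  .gaborBankCache
}

# ---- batched FFT correlation -------------------------------------------
# The slice context applies ~90 kernels per B-scan; doing each through a
# separate FFT convolution wastes two transforms per kernel. Instead the
# (replicate-padded) scan is transformed once and every kernel's cached
# transform is applied in the frequency domain.

smallestSmooth <- function(n) {
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Embed a (2h+1) x (2w+1) kernel at the origin of a dims-sized array with
# circular wrapping, so conj(fft(k)) * fft(m) performs correlation.
embedKernel <- function(kern, dims) {
  kh <- (nrow(kern) - 1L) %/% 2L
  kw <- (ncol(kern) - 1L) %/% 2L
  out <- matrix(0, dims[1L], dims[2L])
  out[((-kh:kh) %% dims[1L]) + 1L, ((-kw:kw) %% dims[2L]) + 1L] <- kern
  out
}

.fftCache <- new.env(parent = emptyenv())

contextKernelList <- function() {
  if (!is.null(.fftCache$kernels)) return(.fftCache$kernels)
  ks <- list()
  bank <- getGaborBank()
  for (m in seq_along(bank)) {
    ks[[sprintf("g%02d_re", m)]] <- bank[[m]]$re
    ks[[sprintf("g%02d_im", m)]] <- bank[[m]]$im
  }
  for (a in names(LAWS_VECTORS)) for (b in names(LAWS_VECTORS))
    ks[[paste0(a, b)]] <- LAWS_VECTORS[[a]] %o% LAWS_VECTORS[[b]]
  .fftCache$kernels <- ks
  ks
}

contextKernelFFTs <- function(dims) {
  key <- paste(dims, collapse = "x")
  if (is.null(.fftCache[[key]])) {
    ks <- contextKernelList()
    .fftCache[[key]] <- lapply(ks, function(k)
      Conj(stats::fft(embedKernel(k, dims))))
  }
  .fftCache[[key]]
}

# Correlate one scan with every context kernel at once (replicate border).
batchCorrelate <- function(scan) {
  ks <- contextKernelList()
  pad <- max(vapply(ks, function(k) (max(dim(k)) - 1L) %/% 2L, integer(1L)))
  mp <- padReplicate(scan, pad)
  dims <- c(smallestSmooth(nrow(mp)), smallestSmooth(ncol(mp)))
  big <- matrix(0, dims[1L], dims[2L])
  big[seq_len(nrow(mp)), seq_len(ncol(mp))] <- mp
  Fm <- stats::fft(big)
  kf <- contextKernelFFTs(dims)
  ri <- (pad + 1L):(pad + nrow(scan))
  ci <- (pad + 1L):(pad + ncol(scan))
  npix <- prod(dims)
  lapply(kf, function(K)
    Re(stats::fft(Fm * K, inverse = TRUE))[ri, ci] / npix)
}

quantize16 <- function(m) {
  q <- floor(m * 16) + 1L
  q[q > 16L] <- 16L
  matrix(as.integer(q), nrow(m), ncol(m))
}

shiftImage <- function(m, dr, dc) {
  ri <- pmin(pmax(seq_len(nrow(m)) + dr, 1L), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m)) + dc, 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

# LBP code image, P = 6 neighbors at radius 1, bilinear interpolation,
# replicate borders. Codes in 0..63; bit k set when neighbor k >= center.
lbpCodes <- function(m) {
  angles <- 2 * pi * (0:5) / 6
  code <- matrix(0L, nrow(m), ncol(m))
  for (k in 0:5) {
    dr <- -sin(angles[k + 1L]); dc <- cos(angles[k + 1L])
    fr <- floor(dr); fc <- floor(dc)
    tr <- dr - fr; tc <- dc - fc
    nb <- (1 - tr) * (1 - tc) * shiftImage(m, fr, fc) +
          (1 - tr) * tc       * shiftImage(m, fr, fc + 1L) +
          tr * (1 - tc)       * shiftImage(m, fr + 1L, fc) +
          tr * tc             * shiftImage(m, fr + 1L, fc + 1L)
    code <- code + as.integer(nb >= m - 1e-12) * bitwShiftL(1L, k)
  }
  code
}

# Per-slice precomputation: every map the per-point features aggregate.
sliceContext <- function(scan) {
  conv <- batchCorrelate(scan)
  gmag <- lapply(seq_along(getGaborBank()), function(m)
    sqrt(conv[[sprintf("g%02d_re", m)]]^2 + conv[[sprintf("g%02d_im", m)]]^2))
  laws <- lapply(LAWS_PAIRS, function(p) {
    if (p[1L] == p[2L]) abs(conv[[paste0(p[1L], p[2L])]])
    else (abs(conv[[paste0(p[1L], p[2L])]]) + abs(conv[[paste0(p[2L], p[1L])]])) / 2
  })
  gy <- gradientY(scan); gx <- gradientX(scan)
  theta <- atan2(gy, gx) %% pi
  bin <- pmin(floor(theta / (pi / 9)) + 1L, 9L)
  list(gabor = gmag, laws = laws, lbp = lbpCodes(scan),
       gradMag = sqrt(gy^2 + gx^2),
       gradBin = matrix(as.integer(bin), nrow(scan), ncol(scan)),
       quant16 = quantize16(scan))
}

# ---- per-category extractors -------------------------------------------

hist16 <- function(v) {
  b <- pmin(floor(v * 16), 15)
  tabulate(b + 1L, 16L) / length(v)
}

stats15 <- function(v) {
  mn <- min(v); mx <- max(v)
  h <- hist5(v)
  c(mean(v), stats::sd(v), mn, mx, stats::median(v), mx - mn,
    safeSkewness(v), safeKurtosis(v), shannonEntropy(h), sum(h^2), h)
}

intensityGlobalFeatures <- function(v) {
  mn <- min(v); mx <- max(v)
  h <- hist16(v)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  c(mean(v), stats::median(v), stats::sd(v), stats::var(v), mn, mx, mx - mn,
    safeSkewness(v), safeKurtosis(v), shannonEntropy(h), sum(h^2),
    q[1L], q[2L])
}

GLCM_OFFSETS <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

# Haralick contrast/correlation/energy/homogeneity on a symmetrized,
# normalized co-occurrence matrix at distance 1 for each of the 4 offsets,
# on a 16-level quantized window. Output order is property-major
# (4 properties x 4 directions).
glcmFeatures <- function(qwin) {
  nr <- nrow(qwin); nc <- ncol(qwin)
  lv <- 16L
  i <- rep(seq_len(lv), times = lv)
  j <- rep(seq_len(lv), each = lv)
  out <- matrix(0, 4L, 4L)   # props x dirs
  for (d in seq_along(GLCM_OFFSETS)) {
    off <- GLCM_OFFSETS[[d]]
    r1 <- max(1L, 1L - off[1L]):min(nr, nr - off[1L])
    c1 <- max(1L, 1L - off[2L]):min(nc, nc - off[2L])
    a <- qwin[r1, c1, drop = FALSE]
    b <- qwin[r1 + off[1L], c1 + off[2L], drop = FALSE]
    counts <- tabulate((a - 1L) * lv + b, lv * lv)
    P <- counts + as.vector(t(matrix(counts, lv, lv)))   # symmetrize
    P <- P / sum(P)
    mu <- sum(i * P)                   # symmetric: mu_x == mu_y
    sg2 <- sum((i - mu)^2 * P)
    corr <- if (sg2 < 1e-12) 0 else sum((i - mu) * (j - mu) * P) / sg2
    out[, d] <- c(sum(P * (i - j)^2), corr, sum(P^2),
                  sum(P / (1 + abs(i - j))))
  }
  as.vector(t(out))
}

hogFeatures <- function(magWin, binWin) {
  nr <- nrow(magWin); nc <- ncol(magWin)
  cellR <- pmin((seq_len(nr) - 1L) * 3L %/% nr, 2L)
  cellC <- pmin((seq_len(nc) - 1L) * 3L %/% nc, 2L)
  cell <- outer(cellR, cellC, function(r, cc) r * 3L + cc) + 1L   # 1..9
  idx <- (as.vector(cell) - 1L) * 9L + as.vector(binWin)
  acc <- as.vector(rowsum(c(as.vector(magWin), rep(0, 81L)),
                          c(idx, 1:81)))
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-12) rep(0, 81L) else acc / nrm
}

# ---- PCA basis ----------------------------------------------------------

#' Fit the PCA basis for the pca feature block
#'
#' Computes the mean window and the first 10 orthonormal principal
#' component vectors of a set of vectorized training windows (via SVD of
#' the centered matrix). The basis is stored with the trained model and
#' reused verbatim at prediction time. Component signs are fixed so the
#' largest-magnitude loading of each component is positive.
#'
#' @param windows numeric matrix, one vectorized training window per row
#'   (at least 10 rows, identical window shape).
#' @param nComponents number of components (default 10).
#' @return list with \code{center} (mean window vector), \code{rotation}
#'   (d x nComponents orthonormal matrix) and \code{nComponents}.
#' @export
fitPCABasis <- function(windows, nComponents = 10L) {
  stopifnot(is.matrix(windows))
  if (nrow(windows) < nComponents)
    stop("need at least ", nComponents, " training windows, got ", nrow(windows))
  center <- colMeans(windows)
  xc <- sweep(windows, 2L, center)
  sv <- svd(t(xc), nu = nComponents, nv = 0L)
  rot <- sv$u
  for (k in seq_len(ncol(rot))) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  list(center = center, rotation = rot, nComponents = as.integer(nComponents))
}

# ---- window extraction --------------------------------------------------

#' Extract the rectangular ROI window around one ILM point
#'
#' The window is \code{subSide} wide and \code{5 * subSide} tall, centered
#' laterally on \code{column} and vertically on the (rounded) ILM row, so
#' sub-windows 1-2 lie above the surface, 3 straddles it and 4-5 lie below.
#' Points whose window would leave the image are skipped: the function
#' returns \code{NULL} and the caller excludes the point.
#'
#' @param scan B-scan matrix.
#' @param ilmRows per-column ILM rows (from [segmentILM()]).
#' @param column column index (1-based).
#' @param geom geometry from [windowGeometry()].
#' @return list with \code{window} (the full rectangle), \code{subPatches}
#'   (list of 5 square matrices, top to bottom), \code{rows}, \code{cols};
#'   or \code{NULL} when the window does not fit.
#' @export
extractWindow <- function(scan, ilmRows, column, geom = windowGeometry()) {
  r0 <- as.integer(round(ilmRows[column])) - geom$halfH
  c0 <- column - geom$halfW
  if (c0 < 1L || c0 + geom$subSide - 1L > ncol(scan) ||
      r0 < 1L || r0 + geom$winH - 1L > nrow(scan))
    return(NULL)
  rows <- r0:(r0 + geom$winH - 1L)
  cols <- c0:(c0 + geom$subSide - 1L)
  win <- scan[rows, cols, drop = FALSE]
  subs <- lapply(1:5, function(s)
    win[((s - 1L) * geom$subSide + 1L):(s * geom$subSide), , drop = FALSE])
  list(window = win, subPatches = subs, rows = rows, cols = cols)
}

validColumns <- function(scan, ilmRows, geom) {
  W <- ncol(scan); H <- nrow(scan)
  cols <- seq_len(W)
  r0 <- as.integer(round(ilmRows)) - geom$halfH
  ok <- cols - geom$halfW >= 1L & cols + geom$halfW <= W &
    r0 >= 1L & r0 + geom$winH - 1L <= H
  cols[ok]
}

subWindowMeans <- function(vals, subSide) {
  rs <- .rowSums(vals, nrow(vals), ncol(vals))
  .colSums(matrix(rs, subSide, 5L), subSide, 5L) / (subSide * subSide)
}

# Assemble the 452 features for the given columns of one slice.
extractFeaturesSlice <- function(scan, ilmRows, geom, basis,
                                 columns = NULL, context = NULL) {
  if (is.null(context)) context <- sliceContext(scan)
  if (is.null(columns)) columns <- validColumns(scan, ilmRows, geom)
  nmap <- length(context$gabor)
  X <- matrix(0, length(columns), 452L)
  if (length(columns) == 0L) return(X)
  for (ii in seq_along(columns)) {
    cc <- columns[ii]
    w <- extractWindow(scan, ilmRows, cc, geom)
    if (is.null(w)) stop("window out of bounds at column ", cc,
                         " (use validColumns to pre-filter)")
    rows <- w$rows; cols <- w$cols
    v <- as.vector(w$window)

    pca <- as.vector(crossprod(basis$rotation, v - basis$center))
    glcm <- glcmFeatures(context$quant16[rows, cols, drop = FALSE])
    gab <- numeric(5L * nmap)
    for (m in seq_len(nmap))
      gab[((m - 1L) * 5L + 1L):(m * 5L)] <-
        subWindowMeans(context$gabor[[m]][rows, cols, drop = FALSE], geom$subSide)
    lbp <- tabulate(context$lbp[rows, cols] + 1L, 64L) / length(v)
    laws <- numeric(28L)
    for (m in 1:14) {
      sub <- context$laws[[m]][rows, cols, drop = FALSE]
      laws[2L * m - 1L] <- mean(sub)
      laws[2L * m] <- stats::sd(sub)
    }
    winStats <- unlist(lapply(w$subPatches, function(p) stats15(as.vector(p))),
                       use.names = FALSE)
    glob <- intensityGlobalFeatures(v)
    glih <- hist5(v)
    hog <- hogFeatures(context$gradMag[rows, cols, drop = FALSE],
                       context$gradBin[rows, cols, drop = FALSE])
    X[ii, ] <- c(pca, glcm, gab, lbp, laws, winStats, glob, glih, hog)
  }
  colnames(X) <- featureNames()
  X
}

#' Extract the 452-value feature vector for one ILM point
#'
#' @inheritParams extractWindow
#' @param basis PCA basis from [fitPCABasis()].
#' @param context optional precomputed filter context for this slice
#'   (computed internally when \code{NULL}; pass one when extracting many
#'   points from the same scan).
#' @return named numeric vector of length 452 (all finite), or \code{NULL}
#'   when the window does not fit (border point; the caller excludes it).
#' @export
extractFeatures <- function(scan, ilmRows, column, geom = windowGeometry(),
                            basis, context = NULL) {
  if (is.null(basis) || is.null(basis$rotation))
    stop("PCA basis not trained; call fitPCABasis() first")
  if (is.null(extractWindow(scan, ilmRows, column, geom))) return(NULL)
  X <- extractFeaturesSlice(scan, ilmRows, geom, basis,
                            columns = column, context = context)
  stats::setNames(X[1L, ], featureNames())
}

#' Extract feature vectors for all eligible ILM points of a volume
#'
#' Runs the per-slice filter banks once per B-scan and assembles the
#' 452-value descriptor at every column whose window fits inside the image
#' (border points are excluded and later predicted as background).
#'
#' @param volume an [OCTVolume-class].
#' @param ilm nSlices x width matrix of ILM rows (from [segmentVolume()]).
#' @param geom geometry from [windowGeometry()].
#' @param basis PCA basis from [fitPCABasis()].
#' @return list with \code{X} (n_points x 452 matrix) and \code{pointID}
#'   (data.frame with \code{slice}, \code{column} per row of \code{X}).
#' @export
extractFeatureMatrix <- function(volume, ilm, geom = windowGeometry(), basis) {
  stopifnot(is(volume, "OCTVolume"), nrow(ilm) == nSlices(volume))
  Xs <- vector("list", nSlices(volume))
  ids <- vector("list", nSlices(volume))
  for (s in seq_len(nSlices(volume))) {
    scan <- volume@slices[[s]]
    cols <- validColumns(scan, ilm[s, ], geom)
    Xs[[s]] <- extractFeaturesSlice(scan, ilm[s, ], geom, basis, columns = cols)
    ids[[s]] <- data.frame(slice = rep(s, length(cols)), column = cols)
  }
  list(X = do.call(rbind, Xs), pointID = do.call(rbind, ids))
}

#' Sample raw ROI windows from volumes (for fitting the PCA basis)
#'
#' @param volumes list of [OCTVolume-class] objects.
#' @param ilms list of matching ILM matrices.
#' @param geom geometry from [windowGeometry()].
#' @param n number of windows to draw (uniformly over eligible points).
#' @param seed RNG seed.
#' @return numeric matrix, one vectorized window per row.
#' @export
sampleWindows <- function(volumes, ilms, geom = windowGeometry(), n = 500L,
                          seed = 1L) {
  pool <- list()
  for (vi in seq_along(volumes)) {
    vol <- volumes[[vi]]
    for (s in seq_len(nSlices(vol))) {
      cols <- validColumns(vol@slices[[s]], ilms[[vi]][s, ], geom)
      if (length(cols) > 0L)
        pool[[length(pool) + 1L]] <-
          cbind(vi, s, cols, deparse.level = 0L)
    }
  }
  pool <- do.call(rbind, pool)
  if (nrow(pool) < n) stop("fewer eligible points (", nrow(pool),
                           ") than requested windows (", n, ")")
  sel <- withSeed(seed, sample.int(nrow(pool), n))
  out <- matrix(0, n, geom$winH * geom$subSide)
  for (k in seq_len(n)) {
    p <- pool[sel[k], ]
    w <- extractWindow(volumes[[p[1L]]]@slices[[p[2L]]],
                       ilms[[p[1L]]][p[2L], ], p[3L], geom)
    out[k, ] <- as.vector(w$window)
  }
  out
}
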