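test_that("the ROI window is centered on the ILM point with five stacked sub-windows", {
  scan <- matrix(stats::runif(200 * 100), 200, 100)
  ilm <- rep(121, 100)
  w <- extractWindow(scan, ilm, 61, windowGeometry(15))
  expect_equal(range(w$rows), c(84, 158))     # 75 rows centered on row 121
  expect_equal(range(w$cols), c(54, 68))      # 15 cols centered on col 61
  expect_equal(dim(w$window), c(75L, 15L))
  expect_length(w$subPatches, 5L)
  expect_equal(w$subPatches[[3]], scan[114:128, 54:68])   # straddles the ILM

  # windows that would leave the image signal a skip
  expect_null(extractWindow(scan, ilm, 3, windowGeometry(15)))
  expect_null(extractWindow(scan, rep(20, 100), 50, windowGeometry(15)))
})

test_that("batch FFT correlation matches a direct sliding-window oracle", {
  naive <- function(m, k) {
    kh <- (nrow(k) - 1) / 2; kw <- (ncol(k) - 1) / 2
    out <- matrix(0, nrow(m), ncol(m))
    for (r in seq_len(nrow(m))) for (cc in seq_len(ncol(m))) {
      acc <- 0
      for (dr in -kh:kh) for (dc in -kw:kw) {
        rr <- min(max(r + dr, 1), nrow(m))
        cx <- min(max(cc + dc, 1), ncol(m))
        acc <- acc + k[dr + kh + 1, dc + kw + 1] * m[rr, cx]
      }
      out[r, cc] <- acc
    }
    out
  }
  set.seed(42)
  m <- matrix(stats::runif(12 * 10), 12, 10)
  conv <- ermmap:::batchCorrelate(m)
  for (nm in c("L5E5", "E5L5", "R5R5", "g01_re", "g10_im")) {
    k <- ermmap:::contextKernelList()[[nm]]
    expect_equal(conv[[nm]], naive(m, k), tolerance = 1e-10)
  }
})

test_that("feature vectors have 452 finite values and unit-sum histograms", {
  fx <- featureFixture()
  f <- extractFeatures(slices(fx$vol)[[1]], fx$ilm[1, ], 60,
                       fx$geom, fx$basis)
  expect_length(f, 452L)
  expect_true(all(is.finite(f)))
  expect_identical(names(f), featureNames())

  expect_equal(sum(f[grep("^lbp_", names(f))]), 1, tolerance = 1e-9)
  expect_equal(sum(f[grep("^glih_", names(f))]), 1, tolerance = 1e-9)
  for (s in 1:5)
    expect_equal(sum(f[sprintf("win_s%d_hist%d", s, 1:5)]), 1, tolerance = 1e-9)
})

test_that("constant windows produce degenerate descriptors (one-hot GLIH, zero HOG)", {
  fx <- featureFixture()
  scan <- matrix(0.5, 160, 128)
  f <- extractFeatures(scan, rep(70, 128), 60, fx$geom, fx$basis)
  expect_true(all(is.finite(f)))
  expect_equal(unname(f[grep("^glih_", names(f))]), c(0, 0, 1, 0, 0))
  expect_true(all(f[grep("^hog_", names(f))] == 0))
  w <- extractWindow(scan, rep(70, 128), 60, fx$geom)
  expect_true(all(vapply(w$subPatches, function(p) all(p == 0.5), logical(1))))
})

test_that("intensity statistics are invariant to left-right mirroring", {
  fx <- featureFixture()
  scan <- slices(fx$vol)[[2]]
  mirrored <- scan[, rev(seq_len(ncol(scan)))]
  ilm <- fx$ilm[2, ]
  cc <- 45L
  f1 <- extractFeatures(scan, ilm, cc, fx$geom, fx$basis)
  f2 <- extractFeatures(mirrored, rev(ilm), ncol(scan) + 1L - cc,
                        fx$geom, fx$basis)
  sel <- grep("^(glih_|glob_)", names(f1))
  expect_equal(f1[sel], f2[sel], tolerance = 1e-12)
})

test_that("the PCA basis is orthonormal, centered, and improves with rank", {
  set.seed(7)
  d <- 75L
  train <- matrix(stats::runif(40 * d), 40, d)
  held <- matrix(stats::runif(10 * d), 10, d)
  basis <- fitPCABasis(train)
  expect_equal(crossprod(basis$rotation), diag(10), tolerance = 1e-8)
  expect_equal(as.vector(crossprod(basis$rotation, colMeans(train) - basis$center)),
               rep(0, 10), tolerance = 1e-10)

  recErr <- function(k) {
    rot <- basis$rotation[, 1:k, drop = FALSE]
    sum(vapply(seq_len(nrow(held)), function(i) {
      xc <- held[i, ] - basis$center
      sum((xc - rot %*% crossprod(rot, xc))^2)
    }, numeric(1)))
  }
  expect_lte(recErr(10), recErr(5))
  expect_error(fitPCABasis(train[1:5, ]), "at least 10")
})

test_that("prediction without a trained PCA basis is a state error", {
  fx <- featureFixture()
  expect_error(extractFeatures(slices(fx$vol)[[1]], fx$ilm[1, ], 60,
                               fx$geom, basis = NULL),
               "basis not trained")
})

test_that("raising the ERM reflectivity raises the above-surface window means", {
  mk <- function(level) {
    spec <- flatSpec(nSlices = 2L, regions = list(c(1, 2, 30, 90, 0)),
                     sigma = 0, seed = 2L, ermLevel = level)
    generatePhantom(spec)
  }
  fx <- featureFixture()
  lo <- mk(170); hi <- mk(240)
  featAt <- function(vol) {
    ilm <- trueILM(vol)
    fm <- extractFeatureMatrix(vol, ilm, fx$geom, fx$basis)
    y <- pointLabels(fm$pointID, trueMap(vol))
    mean(fm$X[y == 1, "win_s3_mean"])
  }
  expect_gt(featAt(hi), featAt(lo))
})

test_that("window features separate ERM from non-ERM points on a noiseless phantom", {
  fx <- featureFixture()
  fm <- extractFeatureMatrix(fx$vol, fx$ilm, fx$geom, fx$basis)
  y <- pointLabels(fm$pointID, trueMap(fx$vol))
  wcols <- which(featureCategories() == "window")
  best <- max(vapply(wcols, function(j) {
    th <- mean(tapply(fm$X[, j], y, mean))
    max(mean((fm$X[, j] > th) == y), mean((fm$X[, j] <= th) == y))
  }, numeric(1)))
  expect_gt(best, 0.8)
})
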