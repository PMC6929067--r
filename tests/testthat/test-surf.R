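test_that("a perfectly separating feature outranks pure-noise features", {
  set.seed(31)
  y <- rep(c(0L, 1L), each = 6L)
  X <- cbind(sep = y + stats::rnorm(12, 0, 0.05),
             n1 = stats::rnorm(12), n2 = stats::rnorm(12), n3 = stats::rnorm(12))
  r <- surfRank(X, y)
  expect_equal(rankingOrder(r)[1], 1L)
  expect_equal(rankingWeights(r), stats::setNames(surfBruteForce(X, y), colnames(X)),
               tolerance = 1e-10)
})

test_that("surfRank matches the brute-force reference on random sample sets", {
  for (seed in 1:10) {
    ss <- randomSampleSet(seed)
    got <- unname(rankingWeights(surfRank(ss$X, ss$y)))
    expect_equal(got, surfBruteForce(ss$X, ss$y), tolerance = 1e-10,
                 label = sprintf("seed %d", seed))
  }
})

test_that("duplicated features get equal weights and constant features weight zero", {
  set.seed(5)
  y <- rep(c(0L, 1L), 8L)
  X <- cbind(a = stats::rnorm(16, y), b = stats::rnorm(16), const = rep(3, 16))
  X <- cbind(X, a2 = X[, "a"])
  w <- rankingWeights(surfRank(X, y))
  expect_equal(unname(w["a"]), unname(w["a2"]), tolerance = 1e-12)
  expect_identical(unname(w["const"]), 0)
})

test_that("weights are invariant to sample order (all-pairs algorithm)", {
  set.seed(8)
  ss <- randomSampleSet(99)
  perm <- sample(nrow(ss$X))
  w1 <- unname(rankingWeights(surfRank(ss$X, ss$y)))
  w2 <- unname(rankingWeights(surfRank(ss$X[perm, ], ss$y[perm])))
  expect_equal(w1, w2, tolerance = 1e-12)
})

test_that("informative features outrank noise features across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 40L
    y <- rep(c(0L, 1L), each = n / 2L)
    X <- cbind(matrix(stats::rnorm(n * 3L, mean = 2 * y), n, 3L),   # informative
               matrix(stats::rnorm(n * 3L), n, 3L))                 # noise
    top3 <- sort(rankingOrder(surfRank(X, y))[1:3])
    hits <- hits + as.integer(identical(top3, 1:3))
  }
  expect_gte(hits / 20, 0.95)
})

test_that("selectTop returns nested prefixes and validates k", {
  set.seed(2)
  ss <- randomSampleSet(7)
  r <- surfRank(ss$X, ss$y)
  p <- ncol(ss$X)
  expect_identical(selectTop(r, p), rankingOrder(r))
  for (k in seq_len(p - 1L))
    expect_identical(selectTop(r, k), selectTop(r, k + 1L)[seq_len(k)])
  expect_error(selectTop(r, 0), "k must be")
  expect_error(selectTop(r, p + 1L), "k must be")
})

test_that("single-class input is rejected", {
  X <- matrix(stats::rnorm(20), 10, 2)
  expect_error(surfRank(X, rep(1L, 10)), "without both classes")
})

test_that("selectTop returns 159 indices from a full 452-feature ranking", {
  set.seed(6)
  w <- stats::runif(452)
  r <- new("FeatureRanking", weights = w,
           order = as.integer(order(-w, seq_along(w))),
           featureNames = featureNames())
  idx <- selectTop(r, 159L)
  expect_length(idx, 159L)
  expect_identical(idx, rankingOrder(r)[1:159])
})
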