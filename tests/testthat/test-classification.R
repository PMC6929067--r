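makeBlobs <- function(n, p = 6L, sep = 3, sd = 0.5, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(stats::rnorm(n * p, mean = sep * y, sd = sd), n, p)
  colnames(X) <- sprintf("f%d", seq_len(p))
  list(X = X, y = y)
}

test_that("training samples are balanced, reproducible, and fail loudly when a class runs out", {
  b <- makeBlobs(200)
  ts <- sampleTrainingSet(b$X, b$y, 100, seed = 4L)
  expect_equal(sum(ts$y == 1), 50L)
  expect_equal(sum(ts$y == 0), 50L)
  expect_identical(ts$idx, sampleTrainingSet(b$X, b$y, 100, seed = 4L)$idx)
  expect_false(identical(ts$idx, sampleTrainingSet(b$X, b$y, 100, seed = 5L)$idx))

  # odd n: ceiling(n/2) positives
  expect_equal(sum(sampleTrainingSet(b$X, b$y, 31, seed = 1L)$y == 1), 16L)
  expect_error(sampleTrainingSet(b$X, b$y, 1000, seed = 1L),
               "class exhausted.*500.*available")
})

test_that("all five classifiers reach accuracy 1 on separable data in 10-fold CV", {
  b <- makeBlobs(200, sep = 6, sd = 0.3)
  r <- surfRank(b$X, b$y)
  for (kind in c("rf", "svm", "knn2", "knn6", "knn8")) {
    cv <- crossValidate(b$X, b$y, kind, 4L, r, seed = 2L)
    expect_length(cv$folds, 10L)
    expect_equal(cv$mean, mean(cv$folds))
    expect_equal(cv$mean, 1, tolerance = 1e-12, label = kind)
  }
})

test_that("randomly permuted labels give chance-level CV accuracy", {
  b <- makeBlobs(300, sep = 4, sd = 0.4, seed = 9L)
  set.seed(77)
  yPerm <- sample(b$y)
  r <- surfRank(b$X, yPerm)
  for (kind in c("svm", "knn6")) {
    cv <- crossValidate(b$X, yPerm, kind, 4L, r, seed = 3L)
    expect_gte(cv$mean, 0.4)
    expect_lte(cv$mean, 0.6)
  }
})

test_that("CV rejects data too small for stratified 10-fold", {
  b <- makeBlobs(12)
  r <- surfRank(b$X, b$y)
  expect_error(crossValidate(b$X, b$y, "rf", 2L, r), "at least 10")
})

test_that("accuracy equals (TP+TN)/n on a hand-checked 10-sample toy", {
  b <- makeBlobs(10, sep = 2, sd = 1, seed = 12L)
  model <- trainERMClassifier(b$X, b$y, "knn8", 1:6)
  pred <- predictPoints(model, b$X)
  tp <- sum(pred == 1 & b$y == 1); tn <- sum(pred == 0 & b$y == 0)
  expect_equal(mean(pred == b$y), (tp + tn) / 10)
})

test_that("kNN vote ties are broken toward the background class", {
  X <- rbind(c(0, 0), c(1, 1))
  model <- trainERMClassifier(X, c(0L, 1L), "knn2", 1:2)
  # with k = 2 and one training point per class, every query ties 1-1
  probe <- rbind(c(0.9, 0.9), c(0.1, 0.1), c(0.5, 0.5))
  expect_equal(predictPoints(model, probe), c(0L, 0L, 0L))
})

test_that("model serialization round-trips predictions exactly", {
  b <- makeBlobs(60, seed = 6L)
  for (kind in c("rf", "svm", "knn6")) {
    model <- trainERMClassifier(b$X, b$y, kind, c(1L, 3L, 5L), seed = 8L)
    path <- tempfile(fileext = ".rds")
    saveERMModel(model, path)
    restored <- loadERMModel(path)
    expect_identical(predictPoints(restored, b$X), predictPoints(model, b$X),
                     label = kind)
  }
})

test_that("feature-length mismatches are errors, not silent truncation", {
  b <- makeBlobs(60)
  model <- trainERMClassifier(b$X, b$y, "svm", 1:4)
  expect_error(predictPoints(model, b$X[, 1:5]), "feature-length mismatch")
})

test_that("the sweep table has the right shape and best-k reproduces the argmax", {
  b <- makeBlobs(200, sep = 1.2, sd = 1, seed = 3L)
  r <- surfRank(b$X, b$y)
  sw <- sweepFeatureCounts(b$X, b$y, r, kGrid = c(2L, 4L, 6L),
                           kinds = c("knn6", "rf"), seed = 1L, nFolds = 10L)
  expect_equal(dim(sw$table), c(2L, 3L))
  for (i in 1:2) {
    gi <- which.max(sw$table[i, ])
    expect_equal(sw$best$k[i], c(2L, 4L, 6L)[gi])
    expect_equal(sw$best$accuracy[i], sw$table[i, gi])
  }
})

test_that("CV and the sweep are deterministic for a fixed seed", {
  b <- makeBlobs(100, sep = 1.5, sd = 1, seed = 21L)
  r <- surfRank(b$X, b$y)
  cv1 <- crossValidate(b$X, b$y, "rf", 3L, r, seed = 11L)
  cv2 <- crossValidate(b$X, b$y, "rf", 3L, r, seed = 11L)
  expect_identical(cv1, cv2)
})

test_that("per-slice prediction labels ERM columns and leaves ERM-free slices clean", {
  fx <- featureFixture()
  fm <- extractFeatureMatrix(fx$vol, fx$ilm, fx$geom, fx$basis)
  y <- pointLabels(fm$pointID, trueMap(fx$vol))
  ts <- sampleTrainingSet(fm$X, y, 200L, seed = 2L)
  ranking <- surfRank(ts$X, ts$y, featureNames())
  model <- trainERMClassifier(ts$X, ts$y, "svm", selectTop(ranking, 60L),
                              basis = fx$basis, geom = fx$geom, seed = 3L)

  s <- 2L
  pred <- predictSlice(model, slices(fx$vol)[[s]], fx$ilm[s, ])
  truth <- mapGrid(trueMap(fx$vol))[s, ]
  cols <- ermmap:::validColumns(slices(fx$vol)[[s]], fx$ilm[s, ], fx$geom)
  expect_gte(mean(pred[cols] == truth[cols]), 0.9)
  # border columns without a full window are background by contract
  expect_true(all(pred[-cols] == 0L))

  free <- generatePhantom(flatSpec(nSlices = 1L, seed = 33L))
  predFree <- predictSlice(model, slices(free)[[1]])
  expect_gte(mean(predFree == 0L), 0.98)
})
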