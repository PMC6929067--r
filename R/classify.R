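# Per-point ERM classification: balanced training-set sampling, model
# fitting (RF / RBF-SVM / kNN with k = 2, 6, 8), stratified 10-fold
# cross-validation, and the feature-count sweep used to pick the operating
# configuration.

CLASSIFIER_KINDS <- c("rf", "svm", "knn2", "knn6", "knn8")

#' Point labels from a ground-truth map
#'
#' @param pointID data.frame with \code{slice}, \code{column} (as produced
#'   by [extractFeatureMatrix()]).
#' @param truth an [ERMMap-class] or binary matrix of ground truth.
#' @return integer vector of 0/1 labels, one per point.
#' @export
pointLabels <- function(pointID, truth) {
  grid <- asMapMatrix(truth)
  as.integer(grid[cbind(pointID$slice, pointID$column)])
}

#' Draw a balanced training sample of ILM points
#'
#' Draws exactly \code{ceiling(n/2)} positive and \code{floor(n/2)}
#' negative points uniformly without replacement from the eligible points,
#' reproducibly for a fixed seed.
#'
#' @param X feature matrix (points x features).
#' @param y binary point labels.
#' @param n total sample size.
#' @param seed RNG seed.
#' @return list with \code{X}, \code{y} and \code{idx} (row indices into
#'   the input).
#' @export
sampleTrainingSet <- function(X, y, n, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  nPos <- ceiling(n / 2); nNeg <- floor(n / 2)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (length(pos) < nPos || length(neg) < nNeg)
    stop(sprintf(
      "class exhausted: need %d positive / %d negative points but only %d / %d available",
      nPos, nNeg, length(pos), length(neg)))
  idx <- withSeed(seed, {
    c(pos[sample.int(length(pos), nPos)], neg[sample.int(length(neg), nNeg)])
  })
  list(X = X[idx, , drop = FALSE], y = y[idx], idx = idx)
}

scaleParams <- function(X) {
  lo <- apply(X, 2L, min)
  rng <- apply(X, 2L, max) - lo
  rng[rng < 1e-12] <- 1
  list(min = lo, range = rng)
}

applyScale <- function(X, sp) sweep(sweep(X, 2L, sp$min), 2L, sp$range, "/")

knnK <- function(kind) as.integer(sub("knn", "", kind))

fitClassifier <- function(kind, X, y, hyper = list(), seed = 1L) {
  yf <- factor(y, levels = c(0L, 1L))
  switch(kind,
    rf = withSeed(seed, randomForest::randomForest(
      x = X, y = yf, ntree = if (is.null(hyper$rfTrees)) 100L else hyper$rfTrees)),
    svm = e1071::svm(
      x = X, y = yf, kernel = "radial", scale = FALSE,
      cost = if (is.null(hyper$svmCost)) 1 else hyper$svmCost,
      gamma = if (is.null(hyper$svmGamma)) 1 / ncol(X) else hyper$svmGamma),
    knn2 = ,
    knn6 = ,
    knn8 = list(train = X, cl = y, k = knnK(kind)),
    stop("unknown classifier kind: ", kind))
}

predictFitted <- function(kind, fit, X) {
  if (kind %in% c("rf", "svm")) {
    if (kind == "svm" && ncol(X) != ncol(fit$SV))
      stop("feature-length mismatch: model expects ", ncol(fit$SV),
           " features, got ", ncol(X))
    return(as.integer(as.character(stats::predict(fit, X))))
  }
  if (ncol(X) != ncol(fit$train))
    stop("feature-length mismatch: model expects ", ncol(fit$train),
         " features, got ", ncol(X))
  pred <- withSeed(0L, class::knn(fit$train, X, factor(fit$cl, levels = c(0L, 1L)),
                                  k = fit$k, prob = TRUE, use.all = TRUE))
  out <- as.integer(as.character(pred))
  # vote ties (winning proportion 1/2) are broken conservatively toward
  # the background class
  out[attr(pred, "prob") <= 0.5] <- 0L
  out
}

#' Train an ERM point classifier
#'
#' Learns per-feature min-max scaling on the training set, fits the chosen
#' classifier on the selected features, and bundles everything prediction
#' needs (scaling, feature subset, PCA basis, window geometry, snake
#' parameters) into an [ERMModel-class]. Nothing is refit at prediction
#' time.
#'
#' @param X training feature matrix (full 452-column registry order).
#' @param y binary labels.
#' @param kind one of \code{"rf"}, \code{"svm"}, \code{"knn2"},
#'   \code{"knn6"}, \code{"knn8"}.
#' @param featureIdx integer indices of the selected features (e.g. from
#'   [selectTop()]).
#' @param basis PCA basis used during feature extraction.
#' @param geom window geometry used during feature extraction.
#' @param snake snake parameters used for ILM segmentation.
#' @param hyper optional list of hyper-parameters (\code{svmCost},
#'   \code{svmGamma}, \code{rfTrees}).
#' @param seed RNG seed (random forest bootstrap).
#' @param metadata free-form list stored with the model.
#' @return an [ERMModel-class].
#' @export
trainERMClassifier <- function(X, y, kind, featureIdx,
                               basis = NULL, geom = windowGeometry(),
                               snake = snakeParams(), hyper = list(),
                               seed = 1L, metadata = list()) {
  stopifnot(kind %in% CLASSIFIER_KINDS)
  sp <- scaleParams(X)
  Xs <- applyScale(X, sp)[, featureIdx, drop = FALSE]
  fit <- fitClassifier(kind, Xs, y, hyper, seed)
  new("ERMModel", classifierKind = kind, featureIdx = as.integer(featureIdx),
      scaleMin = sp$min, scaleRange = sp$range, fit = fit,
      pcaBasis = if (is.null(basis)) list() else basis,
      geometry = geom, snake = snake,
      metadata = c(metadata, list(seed = seed, hyper = hyper)))
}

#' Predict ERM presence for a matrix of feature vectors
#'
#' Applies the stored scaling and feature subset, then the fitted
#' classifier.
#'
#' @param model an [ERMModel-class].
#' @param X feature matrix in full registry order (one row per point).
#' @return integer vector of 0/1 predictions.
#' @export
predictPoints <- function(model, X) {
  stopifnot(is(model, "ERMModel"), is.matrix(X))
  if (ncol(X) != length(model@scaleMin))
    stop("feature-length mismatch: model expects ", length(model@scaleMin),
         " features, got ", ncol(X))
  sp <- list(min = model@scaleMin, range = model@scaleRange)
  Xs <- applyScale(X, sp)[, model@featureIdx, drop = FALSE]
  predictFitted(model@classifierKind, model@fit, Xs)
}

#' Predict the per-column ERM labels of one B-scan
#'
#' Segments the ILM with the model's stored snake parameters, extracts
#' features at every eligible column and classifies them. Columns without a
#' full window (image borders) are labeled 0.
#'
#' @param model an [ERMModel-class].
#' @param scan B-scan matrix.
#' @param ilmRows optional precomputed ILM rows (skips segmentation).
#' @return integer vector of length \code{ncol(scan)}.
#' @export
predictSlice <- function(model, scan, ilmRows = NULL) {
  if (is.null(ilmRows))
    ilmRows <- as.vector(segmentILM(scan, do.call(snakeParams, model@snake)))
  geom <- model@geometry
  cols <- validColumns(scan, ilmRows, geom)
  out <- integer(ncol(scan))
  if (length(cols) == 0L) return(out)
  X <- extractFeaturesSlice(scan, ilmRows, geom, model@pcaBasis, columns = cols)
  out[cols] <- predictPoints(model, X)
  out
}

#' Predict the en-face ERM map of a whole volume
#'
#' @param model an [ERMModel-class].
#' @param volume an [OCTVolume-class].
#' @param ilm optional precomputed ILM matrix.
#' @return a raw [ERMMap-class].
#' @export
predictVolumeMap <- function(model, volume, ilm = NULL) {
  stopifnot(is(volume, "OCTVolume"))
  if (is.null(ilm))
    ilm <- segmentVolume(volume, do.call(snakeParams, model@snake))
  rowsList <- lapply(seq_len(nSlices(volume)), function(s)
    predictSlice(model, volume@slices[[s]], ilm[s, ]))
  buildMap(rowsList)
}

stratifiedFolds <- function(y, nFolds, seed) {
  fold <- integer(length(y))
  withSeed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of one configuration
#'
#' The ranking is applied as a fixed index set (one global ranking, as in
#' the feature-count sweep protocol); min-max scaling is re-learned on each
#' training fold. Folds are stratified and reproducible by seed.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param kind classifier kind (see [trainERMClassifier()]).
#' @param kFeatures number of top-ranked features to use.
#' @param ranking a [FeatureRanking-class].
#' @param seed RNG seed (fold assignment and RF bootstrap).
#' @param nFolds number of folds (default 10).
#' @param hyper hyper-parameter list.
#' @return list with \code{folds} (per-fold accuracies), \code{mean},
#'   \code{kind}, \code{nFeatures}.
#' @export
crossValidate <- function(X, y, kind, kFeatures, ranking, seed = 1L,
                          nFolds = 10L, hyper = list()) {
  y <- as.integer(y)
  if (min(table(factor(y, levels = c(0L, 1L)))) < nFolds)
    stop("need at least ", nFolds, " samples per class for ", nFolds, "-fold CV")
  featureIdx <- selectTop(ranking, kFeatures)
  fold <- stratifiedFolds(y, nFolds, seed)
  accs <- numeric(nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    sp <- scaleParams(X[tr, , drop = FALSE])
    Xtr <- applyScale(X[tr, , drop = FALSE], sp)[, featureIdx, drop = FALSE]
    Xte <- applyScale(X[!tr, , drop = FALSE], sp)[, featureIdx, drop = FALSE]
    fit <- fitClassifier(kind, Xtr, y[tr], hyper, seed + f)
    pred <- predictFitted(kind, fit, Xte)
    accs[f] <- mean(pred == y[!tr])
  }
  list(folds = accs, mean = mean(accs), kind = kind,
       nFeatures = as.integer(kFeatures))
}

#' Sweep the number of selected features across classifiers
#'
#' Evaluates [crossValidate()] over a grid of feature counts for each
#' classifier kind, reports the accuracy table, and selects the per-
#' classifier optimum (ties towards fewer features). With
#' \code{refine = TRUE} the coarse argmax is refined by unit steps within
#' \code{refineRadius}.
#'
#' @param X,y,ranking,seed,nFolds,hyper as in [crossValidate()].
#' @param kGrid feature counts to evaluate.
#' @param kinds classifier kinds to evaluate.
#' @param refine unit-step refinement around the coarse argmax.
#' @param refineRadius half-width (in features) of the refinement window.
#' @return list with \code{table} (kinds x kGrid mean accuracies) and
#'   \code{best} (data.frame with \code{kind}, \code{k}, \code{accuracy}).
#' @export
sweepFeatureCounts <- function(X, y, ranking, kGrid = seq(20L, 200L, 20L),
                               kinds = CLASSIFIER_KINDS, seed = 1L,
                               nFolds = 10L, hyper = list(),
                               refine = FALSE, refineRadius = 10L) {
  kGrid <- as.integer(kGrid)
  tab <- matrix(NA_real_, length(kinds), length(kGrid),
                dimnames = list(kinds, as.character(kGrid)))
  for (ki in seq_along(kinds)) for (gi in seq_along(kGrid))
    tab[ki, gi] <- crossValidate(X, y, kinds[ki], kGrid[gi], ranking,
                                 seed = seed, nFolds = nFolds,
                                 hyper = hyper)$mean
  best <- data.frame(kind = kinds, k = NA_integer_, accuracy = NA_real_,
                     stringsAsFactors = FALSE)
  for (ki in seq_along(kinds)) {
    gi <- which.max(tab[ki, ])                    # first max: smaller k wins ties
    kBest <- kGrid[gi]; aBest <- tab[ki, gi]
    if (refine) {
      ks <- setdiff(max(1L, kBest - refineRadius):
                      min(length(ranking@weights), kBest + refineRadius), kGrid)
      for (k in ks) {
        a <- crossValidate(X, y, kinds[ki], k, ranking, seed = seed,
                           nFolds = nFolds, hyper = hyper)$mean
        if (a > aBest || (a == aBest && k < kBest)) { aBest <- a; kBest <- k }
      }
    }
    best$k[ki] <- kBest; best$accuracy[ki] <- aBest
  }
  list(table = tab, best = best)
}

#' Grid-search SVM hyper-parameters at a fixed feature count
#'
#' Run once, before the feature-count sweep, to establish the SVM baseline
#' configuration: cost over \code{costs} and gamma over the \code{1/k}
#' heuristic times \code{gammaFactors}, scored by stratified CV accuracy.
#'
#' @param X,y,ranking,seed as in [crossValidate()].
#' @param kFeatures feature count to tune at.
#' @param costs,gammaFactors the grid.
#' @param nFolds CV folds used for scoring (default 5 to keep the search
#'   affordable).
#' @return list with \code{svmCost}, \code{svmGamma}, \code{accuracy}.
#' @export
tuneSVM <- function(X, y, ranking, kFeatures = 100L, seed = 1L,
                    costs = c(0.1, 1, 10, 100), gammaFactors = c(0.1, 1, 10),
                    nFolds = 5L) {
  gammaBase <- 1 / kFeatures
  best <- list(svmCost = costs[1L], svmGamma = gammaBase * gammaFactors[1L],
               accuracy = -Inf)
  for (cost in costs) for (gf in gammaFactors) {
    hyper <- list(svmCost = cost, svmGamma = gammaBase * gf)
    a <- crossValidate(X, y, "svm", kFeatures, ranking, seed = seed,
                       nFolds = nFolds, hyper = hyper)$mean
    if (a > best$accuracy)
      best <- list(svmCost = cost, svmGamma = hyper$svmGamma, accuracy = a)
  }
  best
}

#' Save / load a trained model bundle
#'
#' @param model an [ERMModel-class].
#' @param path file path for the serialized bundle.
#' @return \code{loadERMModel}: the restored [ERMModel-class].
#' @export
saveERMModel <- function(model, path) {
  stopifnot(is(model, "ERMModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveERMModel
#' @export
loadERMModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "ERMModel"))
  validObject(model)
  model
}
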