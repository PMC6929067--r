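# End-to-end orchestration: phantom study generation, segmentation,
# feature extraction, selection, training, map reconstruction, refinement
# and evaluation, with one seed funnelling every source of randomness.

#' Default run configuration
#'
#' Collects every tunable of every stage with defaults reproducing the
#' package's reference configuration. Any subset can be overridden via
#' \code{...} (named nested lists are merged recursively), or loaded from a
#' JSON/YAML file with [readRunConfig()].
#'
#' @param ... named overrides, e.g.
#'   \code{ermConfig(snake = list(pressure = 3))}.
#' @return nested configuration list.
#' @export
ermConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    study = list(nTrain = 5L, nTestERM = 5L, nTestFree = 3L,
                 nTrainingSamples = 2000L, nBasisWindows = 400L),
    phantom = list(nSlices = 32L, height = 160L, width = 128L,
                   ilmBaselineRow = 70, ilmCurvatureAmp = 12,
                   ilmWobbleAmp = 3, retinaThickness = 60,
                   tissueLevel = 120, vitreousLevel = 25, ermLevel = 200,
                   speckleSigma = 0.1, ermThickness = 2L),
    snake = snakeParams(),
    geometry = list(subSide = 15L),
    selector = list(kGrid = seq(20L, 200L, 20L), refine = FALSE,
                    refineRadius = 10L),
    classifier = list(kinds = CLASSIFIER_KINDS, nFolds = 10L,
                      tune = TRUE, tuneK = 100L,
                      defaultKind = "svm", defaultK = 160L),
    postprocess = list(minAreaGrid = c(0L, 10L, 25L, 50L, 100L, 200L),
                       closingRadiusGrid = c(0L, 1L, 2L, 3L, 5L, 7L),
                       connectivity = 8L))
  mergeConfig(cfg, list(...))
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration from JSON or YAML
#'
#' Missing fields fall back to the [ermConfig()] defaults.
#'
#' @param path path to a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  override <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext))
  mergeConfig(ermConfig(), override)
}

# Draw the ERM region layout for one phantom volume: 1-2 contiguous
# lateral extents, kept clear of the image borders so the feature window
# always fits, mostly attached (detach 0) with occasional 2-px detachment.
sampleErmRegions <- function(nSlices, width, margin = 10L) {
  nReg <- sample(1:2, 1L)
  regions <- vector("list", nReg)
  for (i in seq_len(nReg)) {
    s0 <- sample.int(max(1L, nSlices - 8L), 1L)
    s1 <- min(nSlices, s0 + sample(8:nSlices, 1L))
    c0 <- sample(margin:(width %/% 2L), 1L)
    c1 <- min(width - margin, c0 + sample(30:80, 1L))
    detach <- sample(c(0L, 0L, 0L, 2L), 1L)
    regions[[i]] <- c(s0, s1, c0, c1, detach)
  }
  regions
}

# Build the study volumes: nTrain + nTestERM phantoms with ERM regions and
# nTestFree without, each with its own derived generator seed.
buildStudyVolumes <- function(cfg, seed) {
  ph <- cfg$phantom
  mkSpec <- function(volSeed, regions)
    do.call(phantomSpec, c(ph, list(ermRegions = regions, rngSeed = volSeed)))
  n <- cfg$study
  withSeed(seed, {
    train <- lapply(seq_len(n$nTrain), function(i)
      generatePhantom(mkSpec(seed + 100L + i,
                             sampleErmRegions(ph$nSlices, ph$width))))
    testERM <- lapply(seq_len(n$nTestERM), function(i)
      generatePhantom(mkSpec(seed + 200L + i,
                             sampleErmRegions(ph$nSlices, ph$width))))
    testFree <- lapply(seq_len(n$nTestFree), function(i)
      generatePhantom(mkSpec(seed + 300L + i, list())))
    list(train = train, testERM = testERM, testFree = testFree)
  })
}

mapFromPoints <- function(pred, pointID, nSlices, width) {
  grid <- matrix(0, nSlices, width)
  grid[cbind(pointID$slice, pointID$column)] <- pred
  new("ERMMap", grid = grid, provenance = "raw")
}

#' Run the full synthetic ERM-mapping study
#'
#' Generates a fixed-seed phantom study (training volumes with ERM, test
#' volumes with and without ERM), then executes the complete pipeline:
#' snake ILM segmentation, PCA basis fitting, 452-feature extraction,
#' balanced training-set sampling, SURF ranking, optional SVM
#' hyper-parameter tuning and feature-count sweep, final model training,
#' per-volume en-face map prediction, post-processing parameter
#' optimization on the training volumes, refinement of all maps, and
#' confusion-matrix evaluation of the test volumes.
#'
#' @param config configuration from [ermConfig()].
#' @param seed master seed; every stage seed is derived from it.
#' @param sweep run the feature-count sweep (slowest stage); when
#'   \code{FALSE} the configured default classifier/feature count is used.
#' @param verbose log per-stage timings to stderr.
#' @return list with the trained \code{model}, SURF \code{ranking}, sweep
#'   results, optimized \code{postprocess} parameters, per-volume maps
#'   (raw/refined/truth), per-volume metric \code{reports}, their
#'   \code{aggregate}, ILM segmentation MAE, and stage \code{timings}.
#' @export
runStudy <- function(config = ermConfig(), seed = config$seed,
                     sweep = TRUE, verbose = TRUE) {
  seed <- as.integer(seed)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, what) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[[what]] <<- dt
    if (verbose) message(sprintf("[ermmap] %-22s %7.1f s", what, dt))
  }

  t0 <- tic()
  vols <- buildStudyVolumes(config, seed)
  allVols <- c(vols$train, vols$testERM, vols$testFree)
  groups <- rep(c("train", "testERM", "testFree"),
                c(length(vols$train), length(vols$testERM), length(vols$testFree)))
  toc(t0, "phantom generation")

  snake <- do.call(snakeParams, config$snake)
  geom <- do.call(windowGeometry, config$geometry)

  t0 <- tic()
  ilms <- lapply(allVols, segmentVolume, params = snake)
  toc(t0, "ILM segmentation")

  t0 <- tic()
  trainIdx <- which(groups == "train")
  basis <- fitPCABasis(sampleWindows(allVols[trainIdx], ilms[trainIdx], geom,
                                     n = config$study$nBasisWindows,
                                     seed = seed + 7L))
  toc(t0, "PCA basis")

  t0 <- tic()
  feats <- lapply(seq_along(allVols), function(i)
    extractFeatureMatrix(allVols[[i]], ilms[[i]], geom, basis))
  toc(t0, "feature extraction")

  t0 <- tic()
  Xtrain <- do.call(rbind, lapply(feats[trainIdx], `[[`, "X"))
  ytrain <- unlist(lapply(trainIdx, function(i)
    pointLabels(feats[[i]]$pointID, trueMap(allVols[[i]]))))
  ts <- sampleTrainingSet(Xtrain, ytrain, config$study$nTrainingSamples,
                          seed = seed + 11L)
  ranking <- surfRank(ts$X, ts$y, featureNames())
  toc(t0, "SURF ranking")

  hyper <- list()
  if (isTRUE(config$classifier$tune)) {
    t0 <- tic()
    tuned <- tuneSVM(ts$X, ts$y, ranking, kFeatures = config$classifier$tuneK,
                     seed = seed + 13L)
    hyper <- list(svmCost = tuned$svmCost, svmGamma = tuned$svmGamma)
    toc(t0, "SVM tuning")
  }

  sweepRes <- NULL
  if (isTRUE(sweep)) {
    t0 <- tic()
    sweepRes <- sweepFeatureCounts(
      ts$X, ts$y, ranking, kGrid = config$selector$kGrid,
      kinds = config$classifier$kinds, seed = seed + 17L,
      nFolds = config$classifier$nFolds, hyper = hyper,
      refine = isTRUE(config$selector$refine),
      refineRadius = config$selector$refineRadius)
    bi <- which.max(sweepRes$best$accuracy)
    bestKind <- sweepRes$best$kind[bi]
    bestK <- sweepRes$best$k[bi]
    toc(t0, "feature-count sweep")
  } else {
    bestKind <- config$classifier$defaultKind
    bestK <- config$classifier$defaultK
  }

  t0 <- tic()
  cv <- crossValidate(ts$X, ts$y, bestKind, bestK, ranking,
                      seed = seed + 19L, nFolds = config$classifier$nFolds,
                      hyper = hyper)
  model <- trainERMClassifier(
    ts$X, ts$y, bestKind, selectTop(ranking, bestK), basis = basis,
    geom = geom, snake = snake, hyper = hyper, seed = seed + 23L,
    metadata = list(cvAccuracy = cv$mean, k = bestK, masterSeed = seed))
  toc(t0, "model training")

  t0 <- tic()
  rawMaps <- lapply(seq_along(allVols), function(i)
    mapFromPoints(predictPoints(model, feats[[i]]$X), feats[[i]]$pointID,
                  nSlices(allVols[[i]]), scanWidth(allVols[[i]])))
  toc(t0, "map prediction")

  t0 <- tic()
  truthMaps <- lapply(allVols, trueMap)
  # the post-processing stage is tuned on the complete study set of
  # ERM-positive volumes (its improvement claim is in-sample for this
  # stage); ERM-free volumes carry no Dice signal
  posIdx <- which(vapply(truthMaps, function(m) any(mapGrid(m) == 1),
                         logical(1L)))
  pp <- optimizePostprocess(rawMaps[posIdx], truthMaps[posIdx],
                            minAreaGrid = config$postprocess$minAreaGrid,
                            closingRadiusGrid = config$postprocess$closingRadiusGrid,
                            connectivity = config$postprocess$connectivity)
  refinedMaps <- lapply(rawMaps, refineMap, params = pp)
  toc(t0, "map refinement")

  reports <- do.call(rbind, lapply(seq_along(allVols), function(i) {
    cls <- if (groups[i] == "testFree") "non-ERM" else "ERM"
    raw <- computeMetrics(confusionCounts(rawMaps[[i]], truthMaps[[i]]),
                          volumeID = volumeID(allVols[[i]]), stage = "classification")
    ref <- computeMetrics(confusionCounts(refinedMaps[[i]], truthMaps[[i]]),
                          volumeID = volumeID(allVols[[i]]), stage = "postprocess")
    cbind(rbind(raw, ref),
          class = cls, group = groups[i], stringsAsFactors = FALSE)
  }))
  testReports <- reports[reports$group != "train", , drop = FALSE]

  ilmMAE <- vapply(seq_along(allVols), function(i)
    mean(abs(ilms[[i]] - trueILM(allVols[[i]]))), numeric(1L))

  list(config = config, seed = seed, groups = groups,
       model = model, ranking = ranking, sweep = sweepRes, hyper = hyper,
       cv = cv, postprocess = pp,
       maps = list(raw = rawMaps, refined = refinedMaps, truth = truthMaps),
       reports = reports, testReports = testReports,
       aggregate = aggregateMetrics(testReports),
       ilmMAE = ilmMAE, timings = timings)
}

#' Run the built-in demonstration study
#'
#' A deterministic end-to-end run of the reduced phantom study without the
#' feature-count sweep (the configured default classifier is used), writing
#' the maps and a JSON metrics summary when \code{outDir} is given.
#'
#' @param seed master seed.
#' @param outDir optional output directory for maps and metrics.
#' @param sweep run the feature-count sweep as well.
#' @param config configuration from [ermConfig()].
#' @return the [runStudy()] result, invisibly.
#' @export
runDemo <- function(seed = 1L, outDir = NULL, sweep = FALSE,
                    config = ermConfig()) {
  res <- runStudy(config, seed = seed, sweep = sweep)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(res$maps$raw)) {
      saveMap(res$maps$raw[[i]], file.path(outDir, sprintf("map_raw_%02d.png", i)))
      saveMap(res$maps$refined[[i]], file.path(outDir, sprintf("map_refined_%02d.png", i)))
      saveMap(res$maps$truth[[i]], file.path(outDir, sprintf("map_truth_%02d.png", i)))
    }
    jsonlite::write_json(
      list(seed = res$seed,
           cvAccuracy = res$cv$mean,
           classifier = classifierKind(res$model),
           nFeatures = length(selectedFeatures(res$model)),
           postprocess = res$postprocess[c("minArea", "closingRadius", "connectivity")],
           aggregate = res$aggregate),
      file.path(outDir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
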