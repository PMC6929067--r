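# Small phantom builders shared across test files.

tinySpec <- function(nSlices = 2L, regions = list(), sigma = 0,
                     seed = 1L, ...) {
  phantomSpec(nSlices = nSlices, ermRegions = regions,
              speckleSigma = sigma, rngSeed = seed, ...)
}

flatSpec <- function(nSlices = 2L, regions = list(), sigma = 0, seed = 1L, ...) {
  tinySpec(nSlices = nSlices, regions = regions, sigma = sigma, seed = seed,
           ilmCurvatureAmp = 0, ilmWobbleAmp = 0, ...)
}

# A tiny volume with a segmented ILM and a fitted PCA basis, for feature
# tests; memoized because several tests reuse it.
.featureFixture <- new.env(parent = emptyenv())
featureFixture <- function() {
  if (is.null(.featureFixture$fx)) {
    spec <- tinySpec(nSlices = 4L, regions = list(c(1, 4, 30, 90, 0)),
                     sigma = 0, seed = 11L)
    vol <- generatePhantom(spec)
    ilm <- segmentVolume(vol)
    geom <- windowGeometry()
    basis <- fitPCABasis(sampleWindows(list(vol), list(ilm), geom,
                                       n = 60L, seed = 3L))
    .featureFixture$fx <- list(vol = vol, ilm = ilm, geom = geom, basis = basis)
  }
  .featureFixture$fx
}
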