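#' @import methods
NULL

#' OCTVolume: an ordered stack of grayscale B-scans
#'
#' Container for one OCT acquisition (a C-scan): an ordered list of 2D
#' B-scan matrices sharing height and width. Row 1 of each matrix is the top
#' of the scan (vitreous side); intensities are stored as doubles in
#' \code{[0, 1]} (8-bit values divided by 255). Slice order is acquisition
#' order and becomes the row order of the en-face ERM map.
#'
#' @slot slices list of numeric matrices, one per B-scan, identical dims.
#' @slot volumeID character scalar identifying the volume.
#' @export
setClass("OCTVolume",
  representation(slices = "list", volumeID = "character"),
  prototype(slices = list(), volumeID = "volume")
)

setValidity("OCTVolume", function(object) {
  s <- object@slices
  if (length(s) == 0L) return("volume must contain at least one slice")
  if (!all(vapply(s, is.matrix, logical(1L))))
    return("all slices must be numeric matrices")
  dims <- vapply(s, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    return("all slices must share height and width")
  rng <- range(unlist(lapply(s, range)))
  if (rng[1L] < 0 || rng[2L] > 1)
    return("slice intensities must lie in [0, 1]")
  if (length(object@volumeID) != 1L) return("volumeID must be a single string")
  TRUE
})

#' PhantomSpec: geometry and intensity parameters of a synthetic OCT volume
#'
#' Describes a layered retinal phantom: dark vitreous above a bright curved
#' ILM surface, tissue below, multiplicative speckle, and optional
#' hyper-reflective ERM bands attached to (or floating just above) the ILM
#' over contiguous lateral extents.
#'
#' Intensity levels are mean 8-bit values and must satisfy
#' \code{ermLevel > tissueLevel > vitreousLevel} (the ERM is
#' hyper-reflective; the vitreous is darkest). ERM regions are given as
#' 5-vectors \code{c(sliceStart, sliceEnd, colStart, colEnd, detachPx)}
#' (1-based, inclusive); \code{detachPx = 0} renders the band attached to
#' the ILM, larger values leave a dark gap below the band.
#'
#' @seealso [phantomSpec()] for the user constructor with study defaults.
#' @export
setClass("PhantomSpec",
  representation(
    nSlices = "integer", height = "integer", width = "integer",
    ilmBaselineRow = "numeric", ilmCurvatureAmp = "numeric",
    ilmWobbleAmp = "numeric", retinaThickness = "numeric",
    tissueLevel = "numeric", vitreousLevel = "numeric", ermLevel = "numeric",
    speckleSigma = "numeric", ermThickness = "integer",
    ermRegions = "list", rngSeed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  ord <- c(object@ermLevel > object@tissueLevel,
           object@tissueLevel > object@vitreousLevel)
  if (!all(ord))
    return("intensity ordering violated: need ermLevel > tissueLevel > vitreousLevel")
  excur <- object@ilmCurvatureAmp + object@ilmWobbleAmp
  lo <- object@ilmBaselineRow - excur
  hi <- object@ilmBaselineRow + excur
  band <- object@ermThickness + maxDetach(object)
  if (lo - band < 1)
    return("ilmBaselineRow too shallow: ERM band would leave the image (check ilmBaselineRow, ilmCurvatureAmp, ilmWobbleAmp, ermThickness, detachPx)")
  if (hi + object@retinaThickness > object@height)
    return("ilmBaselineRow too deep: retina exceeds image height (check ilmBaselineRow, retinaThickness)")
  for (r in object@ermRegions) {
    if (length(r) != 5L)
      return("each ermRegions entry must be c(sliceStart, sliceEnd, colStart, colEnd, detachPx)")
    if (r[1L] < 1 || r[2L] > object@nSlices || r[1L] > r[2L])
      return(sprintf("ermRegions slice range [%d, %d] outside [1, %d]", r[1L], r[2L], object@nSlices))
    if (r[3L] < 1 || r[4L] > object@width || r[3L] > r[4L])
      return(sprintf("ermRegions column range [%d, %d] outside [1, %d]", r[3L], r[4L], object@width))
    if (r[5L] < 0) return("ermRegions detachPx must be >= 0")
  }
  if (object@ermThickness < 1L) return("ermThickness must be >= 1 px")
  if (object@speckleSigma < 0) return("speckleSigma must be >= 0")
  TRUE
})

maxDetach <- function(spec) {
  if (length(spec@ermRegions) == 0L) return(0)
  max(vapply(spec@ermRegions, function(r) r[5L], numeric(1L)))
}

#' PhantomVolume: a synthetic OCT volume with ground truth
#'
#' An [OCTVolume] extended with the generating [PhantomSpec], the true ILM
#' surface (one row coordinate per slice and column) and the true en-face
#' ERM map (binary, one row per slice).
#'
#' @slot spec the generating PhantomSpec.
#' @slot trueILM nSlices x width numeric matrix of ILM row coordinates.
#' @slot trueMap nSlices x width binary matrix (1 = ERM present).
#' @export
setClass("PhantomVolume",
  contains = "OCTVolume",
  representation(spec = "PhantomSpec", trueILM = "matrix", trueMap = "matrix")
)

setValidity("PhantomVolume", function(object) {
  n <- length(object@slices)
  w <- ncol(object@slices[[1L]])
  if (!all(dim(object@trueILM) == c(n, w)))
    return("trueILM must be nSlices x width")
  if (!all(dim(object@trueMap) == c(n, w)))
    return("trueMap must be nSlices x width")
  if (!all(object@trueMap %in% c(0, 1)))
    return("trueMap must be binary")
  TRUE
})

#' ERMMap: binary en-face map of ERM extent
#'
#' One row per B-scan, one column per lateral scan position; cell = 1 where
#' ERM is predicted (or known) present. \code{provenance} records whether
#' the map is a raw per-slice classifier output, a morphologically refined
#' map, or ground truth.
#'
#' @slot grid binary matrix (nSlices x width).
#' @slot provenance one of \code{"raw"}, \code{"refined"}, \code{"truth"}.
#' @export
setClass("ERMMap",
  representation(grid = "matrix", provenance = "character"),
  prototype(provenance = "raw")
)

setValidity("ERMMap", function(object) {
  if (!all(object@grid %in% c(0, 1))) return("map grid must be binary (0/1)")
  if (!object@provenance %in% c("raw", "refined", "truth"))
    return("provenance must be one of 'raw', 'refined', 'truth'")
  TRUE
})

#' FeatureRanking: SURF weights and the induced feature order
#'
#' @slot weights per-feature SURF relevance weight.
#' @slot order integer permutation of features, best first; ties broken by
#'   ascending feature index.
#' @slot featureNames feature names aligned with \code{weights}.
#' @export
setClass("FeatureRanking",
  representation(weights = "numeric", order = "integer", featureNames = "character")
)

setValidity("FeatureRanking", function(object) {
  n <- length(object@weights)
  if (!identical(sort(object@order), seq_len(n)))
    return("order must be a permutation of 1..n_features")
  if (length(object@featureNames) != n)
    return("featureNames must align with weights")
  TRUE
})

#' ERMModel: a trained per-point ERM classifier
#'
#' Bundles everything prediction needs so that no component is ever refit at
#' prediction time: the classifier kind and fitted state, the selected
#' feature indices, the per-feature min-max scaling learned on the training
#' set, the PCA basis used by the pca feature block, and the window/snake
#' parameters the features were extracted under.
#'
#' @slot classifierKind one of \code{"rf"}, \code{"svm"}, \code{"knn2"},
#'   \code{"knn6"}, \code{"knn8"}.
#' @slot featureIdx integer indices (into the 452-feature registry) used by
#'   this model.
#' @slot scaleMin,scaleRange per-feature min and range over the training set
#'   (full registry length); applied before subsetting.
#' @slot fit opaque fitted state (randomForest, svm, or stored kNN training
#'   data).
#' @slot pcaBasis PCA basis list (center + rotation) from [fitPCABasis()].
#' @slot geometry window geometry list from [windowGeometry()].
#' @slot snake snake parameter list from [snakeParams()].
#' @slot metadata free-form list (seeds, CV accuracy, selected k, ...).
#' @export
setClass("ERMModel",
  representation(
    classifierKind = "character", featureIdx = "integer",
    scaleMin = "numeric", scaleRange = "numeric",
    fit = "ANY", pcaBasis = "list", geometry = "list", snake = "list",
    metadata = "list"
  )
)

setValidity("ERMModel", function(object) {
  if (!object@classifierKind %in% c("rf", "svm", "knn2", "knn6", "knn8"))
    return("classifierKind must be one of rf, svm, knn2, knn6, knn8")
  if (length(object@scaleMin) != length(object@scaleRange))
    return("scaleMin and scaleRange must have equal length")
  if (any(object@featureIdx < 1L) || any(object@featureIdx > length(object@scaleMin)))
    return("featureIdx out of range of the feature registry")
  TRUE
})
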