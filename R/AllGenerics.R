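# Accessor generics and show methods.

#' @rdname OCTVolume-class
#' @param object,x an object.
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))
#' @rdname OCTVolume-class
#' @export
setMethod("slices", "OCTVolume", function(x) x@slices)

#' @rdname OCTVolume-class
#' @export
setGeneric("volumeID", function(x) standardGeneric("volumeID"))
#' @rdname OCTVolume-class
#' @export
setMethod("volumeID", "OCTVolume", function(x) x@volumeID)

#' @rdname OCTVolume-class
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname OCTVolume-class
#' @export
setMethod("nSlices", "OCTVolume", function(x) length(x@slices))

#' @rdname OCTVolume-class
#' @export
setGeneric("scanHeight", function(x) standardGeneric("scanHeight"))
#' @rdname OCTVolume-class
#' @export
setMethod("scanHeight", "OCTVolume", function(x) nrow(x@slices[[1L]]))

#' @rdname OCTVolume-class
#' @export
setGeneric("scanWidth", function(x) standardGeneric("scanWidth"))
#' @rdname OCTVolume-class
#' @export
setMethod("scanWidth", "OCTVolume", function(x) ncol(x@slices[[1L]]))

#' @rdname PhantomVolume-class
#' @param x a PhantomVolume.
#' @export
setGeneric("trueILM", function(x) standardGeneric("trueILM"))
#' @rdname PhantomVolume-class
#' @export
setMethod("trueILM", "PhantomVolume", function(x) x@trueILM)

#' @rdname PhantomVolume-class
#' @export
setGeneric("trueMap", function(x) standardGeneric("trueMap"))
#' @rdname PhantomVolume-class
#' @export
setMethod("trueMap", "PhantomVolume",
  function(x) new("ERMMap", grid = x@trueMap, provenance = "truth"))

#' @rdname ERMMap-class
#' @param x an ERMMap.
#' @export
setGeneric("mapGrid", function(x) standardGeneric("mapGrid"))
#' @rdname ERMMap-class
#' @export
setMethod("mapGrid", "ERMMap", function(x) x@grid)

#' @rdname ERMMap-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ERMMap-class
#' @export
setMethod("provenance", "ERMMap", function(x) x@provenance)

#' @rdname FeatureRanking-class
#' @param x a FeatureRanking.
#' @export
setGeneric("rankingWeights", function(x) standardGeneric("rankingWeights"))
#' @rdname FeatureRanking-class
#' @export
setMethod("rankingWeights", "FeatureRanking", function(x) {
  w <- x@weights
  names(w) <- x@featureNames
  w
})

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankingOrder", function(x) standardGeneric("rankingOrder"))
#' @rdname FeatureRanking-class
#' @export
setMethod("rankingOrder", "FeatureRanking", function(x) x@order)

#' @rdname ERMModel-class
#' @param x an ERMModel.
#' @export
setGeneric("classifierKind", function(x) standardGeneric("classifierKind"))
#' @rdname ERMModel-class
#' @export
setMethod("classifierKind", "ERMModel", function(x) x@classifierKind)

#' @rdname ERMModel-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname ERMModel-class
#' @export
setMethod("selectedFeatures", "ERMModel", function(x) x@featureIdx)

setMethod("show", "OCTVolume", function(object) {
  cat(sprintf("%s '%s': %d B-scan(s), %d x %d px, intensities [%.3f, %.3f]\n",
              class(object), object@volumeID, nSlices(object),
              scanHeight(object), scanWidth(object),
              min(unlist(lapply(object@slices, min))),
              max(unlist(lapply(object@slices, max)))))
  if (is(object, "PhantomVolume"))
    cat(sprintf("  ERM ground truth: %d / %d en-face pixels positive\n",
                sum(object@trueMap), length(object@trueMap)))
})

setMethod("show", "ERMMap", function(object) {
  cat(sprintf("ERMMap (%s): %d slices x %d columns, %d positive px (%.1f%%)\n",
              object@provenance, nrow(object@grid), ncol(object@grid),
              sum(object@grid), 100 * mean(object@grid)))
})

setMethod("show", "FeatureRanking", function(object) {
  k <- min(5L, length(object@order))
  top <- object@featureNames[object@order[seq_len(k)]]
  cat(sprintf("FeatureRanking over %d features; top %d: %s\n",
              length(object@weights), k, paste(top, collapse = ", ")))
})

setMethod("show", "ERMModel", function(object) {
  cat(sprintf("ERMModel [%s] on %d selected features",
              object@classifierKind, length(object@featureIdx)))
  if (!is.null(object@metadata$cvAccuracy))
    cat(sprintf(" (CV accuracy %.3f)", object@metadata$cvAccuracy))
  cat("\n")
})
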