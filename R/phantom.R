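#' Construct a synthetic OCT phantom specification
#'
#' The phantom emulates the appearance that drives ERM detection in real
#' macular OCT: a dark vitreous cavity above a bright, curved inner retinal
#' surface (the ILM, with a parabolic foveal dip plus a smooth low-frequency
#' undulation per slice), a band of brighter retinal tissue below it, and —
#' where requested — a thin hyper-reflective ERM band sitting on, or a few
#' pixels above, the ILM over a contiguous lateral extent. Multiplicative
#' speckle (pixel times \code{1 + N(0, sigma)}, clipped to 8 bits) stresses
#' the intensity and texture features.
#'
#' Defaults are the reduced synthetic study conditions used throughout the
#' package's tests and demo: 32 slices of 160 x 128 px with speckle sigma
#' 0.1.
#'
#' @param nSlices number of B-scans in the volume.
#' @param height,width B-scan dimensions in pixels.
#' @param ilmBaselineRow mean ILM depth (row index, 1-based).
#' @param ilmCurvatureAmp depth (px) of the parabolic foveal dip at the
#'   lateral center.
#' @param ilmWobbleAmp amplitude (px) of the smooth per-slice sinusoidal
#'   surface undulation.
#' @param retinaThickness thickness (px) of the bright tissue band below the
#'   ILM.
#' @param tissueLevel,vitreousLevel,ermLevel mean 8-bit intensities; must
#'   satisfy \code{ermLevel > tissueLevel > vitreousLevel}.
#' @param speckleSigma multiplicative speckle scale (0 disables noise).
#' @param ermThickness ERM band thickness in px (1-3 is realistic).
#' @param ermRegions list of 5-vectors
#'   \code{c(sliceStart, sliceEnd, colStart, colEnd, detachPx)} (1-based,
#'   inclusive) marking where the ERM band is rendered; \code{detachPx = 0}
#'   attaches the band to the ILM.
#' @param rngSeed integer seed making the volume bit-reproducible.
#' @return a validated [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(nSlices = 4, ermRegions = list(c(1, 4, 30, 90, 0)))
#' vol <- generatePhantom(spec)
#' vol
#' @export
phantomSpec <- function(nSlices = 32L, height = 160L, width = 128L,
                        ilmBaselineRow = 70, ilmCurvatureAmp = 12,
                        ilmWobbleAmp = 3, retinaThickness = 60,
                        tissueLevel = 120, vitreousLevel = 25, ermLevel = 200,
                        speckleSigma = 0.1, ermThickness = 2L,
                        ermRegions = list(), rngSeed = 1L) {
  new("PhantomSpec",
      nSlices = as.integer(nSlices), height = as.integer(height),
      width = as.integer(width), ilmBaselineRow = ilmBaselineRow,
      ilmCurvatureAmp = ilmCurvatureAmp, ilmWobbleAmp = ilmWobbleAmp,
      retinaThickness = retinaThickness, tissueLevel = tissueLevel,
      vitreousLevel = vitreousLevel, ermLevel = ermLevel,
      speckleSigma = speckleSigma, ermThickness = as.integer(ermThickness),
      ermRegions = lapply(ermRegions, as.numeric), rngSeed = as.integer(rngSeed))
}

#' Generate a synthetic OCT volume with known ILM and ERM ground truth
#'
#' Deterministic for a fixed \code{rngSeed}: the same spec always yields a
#' bit-identical volume. The returned object carries the true ILM surface
#' (the first tissue row per slice/column, after curvature and wobble) and
#' the true en-face ERM map (\code{1} exactly inside the requested
#' \code{ermRegions}, with no blurring applied to the mask).
#'
#' @param spec a [PhantomSpec-class], typically from [phantomSpec()].
#' @return a [PhantomVolume-class].
#' @export
generatePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@nSlices; h <- spec@height; w <- spec@width
  withSeed(spec@rngSeed, {
    freq <- stats::runif(n, 0.5, 2)
    phase <- stats::runif(n, 0, 2 * pi)
    xi <- 2 * (seq_len(w) - (w + 1) / 2) / w          # in (-1, 1)
    base <- spec@ilmBaselineRow + spec@ilmCurvatureAmp * (1 - xi^2)

    ilm <- matrix(0L, n, w)
    mask <- matrix(0, n, w)
    for (r in spec@ermRegions)
      mask[r[1L]:r[2L], r[3L]:r[4L]] <- 1
    detach <- matrix(0, n, w)
    for (r in spec@ermRegions)
      detach[r[1L]:r[2L], r[3L]:r[4L]] <- r[5L]

    slices <- vector("list", n)
    for (s in seq_len(n)) {
      rows <- round(base + spec@ilmWobbleAmp *
                      sin(2 * pi * freq[s] * seq_len(w) / w + phase[s]))
      ilm[s, ] <- as.integer(rows)
      img <- matrix(spec@vitreousLevel, h, w)
      for (cc in seq_len(w)) {
        r0 <- rows[cc]
        img[r0:min(h, r0 + spec@retinaThickness - 1L), cc] <- spec@tissueLevel
        if (mask[s, cc] == 1) {
          top <- r0 - detach[s, cc] - spec@ermThickness
          img[top:(top + spec@ermThickness - 1L), cc] <- spec@ermLevel
        }
      }
      if (spec@speckleSigma > 0)
        img <- img * (1 + matrix(stats::rnorm(h * w, 0, spec@speckleSigma), h, w))
      img <- round(pmin(pmax(img, 0), 255))
      slices[[s]] <- img / 255
    }
    new("PhantomVolume",
        slices = slices,
        volumeID = sprintf("phantom-seed%d", spec@rngSeed),
        spec = spec, trueILM = ilm, trueMap = mask)
  })
}

#' Write a phantom volume to an image-stack directory
#'
#' Saves the B-scans as zero-padded 8-bit grayscale PNGs
#' (\code{slice_0001.png}, ...), the ground-truth map as a binary PNG plus a
#' CSV twin, the true ILM as CSV (\code{slice, column, row}), and a
#' \code{manifest.json} listing the files and embedding the generating spec
#' so the volume can be regenerated bit-identically.
#'
#' @param vol a [PhantomVolume-class].
#' @param dirPath output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
writePhantom <- function(vol, dirPath) {
  stopifnot(is(vol, "PhantomVolume"))
  if (!dir.exists(dirPath) &&
      !dir.create(dirPath, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", dirPath)
  files <- sprintf("slice_%04d.png", seq_len(nSlices(vol)))
  for (s in seq_len(nSlices(vol)))
    png::writePNG(vol@slices[[s]], file.path(dirPath, files[s]))
  saveMap(trueMap(vol), file.path(dirPath, "true_map.png"))
  ilmDF <- data.frame(
    slice = rep(seq_len(nrow(vol@trueILM)), each = ncol(vol@trueILM)),
    column = rep(seq_len(ncol(vol@trueILM)), nrow(vol@trueILM)),
    row = as.vector(t(vol@trueILM)))
  utils::write.csv(ilmDF, file.path(dirPath, "true_ilm.csv"), row.names = FALSE)
  spec <- vol@spec
  manifest <- list(
    volumeID = vol@volumeID,
    files = as.list(files),
    trueMap = "true_map.png", trueILM = "true_ilm.csv",
    spec = list(
      nSlices = spec@nSlices, height = spec@height, width = spec@width,
      ilmBaselineRow = spec@ilmBaselineRow,
      ilmCurvatureAmp = spec@ilmCurvatureAmp,
      ilmWobbleAmp = spec@ilmWobbleAmp,
      retinaThickness = spec@retinaThickness,
      tissueLevel = spec@tissueLevel, vitreousLevel = spec@vitreousLevel,
      ermLevel = spec@ermLevel, speckleSigma = spec@speckleSigma,
      ermThickness = spec@ermThickness,
      ermRegions = lapply(spec@ermRegions, as.numeric),
      rngSeed = spec@rngSeed))
  jsonlite::write_json(manifest, file.path(dirPath, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Rebuild a PhantomSpec from a written manifest
#'
#' @param path path to a \code{manifest.json} written by [writePhantom()].
#' @return the embedded [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- m$spec
  regions <- s$ermRegions
  if (is.null(regions) || length(regions) == 0L) regions <- list()
  else if (is.matrix(regions)) regions <- asplit(regions, 1L)
  else if (!is.list(regions)) regions <- list(regions)
  phantomSpec(nSlices = s$nSlices, height = s$height, width = s$width,
              ilmBaselineRow = s$ilmBaselineRow,
              ilmCurvatureAmp = s$ilmCurvatureAmp,
              ilmWobbleAmp = s$ilmWobbleAmp,
              retinaThickness = s$retinaThickness,
              tissueLevel = s$tissueLevel, vitreousLevel = s$vitreousLevel,
              ermLevel = s$ermLevel, speckleSigma = s$speckleSigma,
              ermThickness = s$ermThickness,
              ermRegions = lapply(regions, as.numeric), rngSeed = s$rngSeed)
}
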