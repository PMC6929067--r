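# Volume and map I/O. Volumes are directories of grayscale PNG/TIFF
# B-scans; slice order is the numeric suffix order of the filenames.
# Intensities are held internally as doubles in [0, 1].

readGrayImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 3L) {
    # refuse to silently collapse colour data; a grayscale scan stored with
    # identical channels is accepted
    ch <- dim(img)[3L]
    planes <- lapply(seq_len(min(ch, 3L)), function(i) img[, , i])
    if (ch >= 2L && !all(vapply(planes[-1L],
                                function(p) isTRUE(all.equal(p, planes[[1L]])),
                                logical(1L))))
      stop("not a grayscale image: ", path)
    img <- planes[[1L]]
  }
  img
}

#' Load an OCT volume from an image-stack directory
#'
#' Reads every \code{.png}/\code{.tif}/\code{.tiff} file in \code{dirPath}
#' (ground-truth files written by [writePhantom()] are skipped), sorts them
#' by the numeric part of the filename (so \code{slice_2} loads before
#' \code{slice_10}), and stacks them into an [OCTVolume-class]. Slices with
#' inconsistent dimensions or colour content are rejected rather than
#' coerced.
#'
#' @param dirPath directory containing the B-scan images.
#' @param volumeID identifier for the volume; defaults to the directory name.
#' @return an [OCTVolume-class].
#' @export
loadVolume <- function(dirPath, volumeID = basename(normalizePath(dirPath))) {
  if (!dir.exists(dirPath)) stop("directory not found: ", dirPath)
  files <- list.files(dirPath, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
  files <- setdiff(files, "true_map.png")
  if (length(files) == 0L) stop("no image files found in: ", dirPath)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", files)))
  num[is.na(num)] <- Inf
  files <- files[order(num, files)]
  slices <- lapply(file.path(dirPath, files), readGrayImage)
  dims <- vapply(slices, dim, integer(2L))
  ref <- dims[, 1L]
  bad <- which(dims[1L, ] != ref[1L] | dims[2L, ] != ref[2L])
  if (length(bad) > 0L)
    stop("inconsistent slice dimensions in: ",
         paste(files[bad], collapse = ", "),
         " (expected ", ref[1L], " x ", ref[2L], ")")
  new("OCTVolume", slices = slices, volumeID = volumeID)
}

#' Save or load an en-face ERM map
#'
#' Maps are serialized losslessly as a binary PNG (white = ERM present)
#' together with a CSV twin listing the positive pixels
#' (\code{slice, column}); \code{loadMap(saveMap(m))} is the identity.
#'
#' @param map an [ERMMap-class] or binary matrix.
#' @param path output PNG path; the CSV twin replaces the extension with
#'   \code{.csv}.
#' @return \code{saveMap}: invisibly, the PNG path. \code{loadMap}: an
#'   [ERMMap-class].
#' @export
saveMap <- function(map, path) {
  grid <- asMapMatrix(map)
  png::writePNG(grid, path)
  pos <- which(grid == 1, arr.ind = TRUE)
  df <- data.frame(slice = pos[, 1L], column = pos[, 2L])
  df <- df[order(df$slice, df$column), , drop = FALSE]
  utils::write.csv(df, sub("\\.png$", ".csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname saveMap
#' @param provenance provenance tag to attach to the loaded map.
#' @export
loadMap <- function(path, provenance = "raw") {
  img <- readGrayImage(path)
  vals <- sort(unique(as.vector(img)))
  if (!all(vals %in% c(0, 1)))
    stop("not a binary map (found intensities other than 0 and 1): ", path)
  new("ERMMap", grid = img, provenance = provenance)
}
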