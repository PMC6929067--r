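# En-face map assembly and morphological refinement.

#' Post-processing parameters for map refinement
#'
#' @param minArea connected components smaller than this many map pixels
#'   are removed.
#' @param closingRadius radius (px) of the disk structuring element of the
#'   binary closing applied after area filtering; 0 disables closing.
#' @param connectivity pixel adjacency for component analysis: 4 or 8
#'   (default 8, so diagonal B-scan-to-B-scan adjacency counts).
#' @return named parameter list.
#' @export
postprocessParams <- function(minArea = 0L, closingRadius = 0L,
                              connectivity = 8L) {
  stopifnot(minArea >= 0, closingRadius >= 0, connectivity %in% c(4L, 8L))
  list(minArea = as.integer(minArea),
       closingRadius = as.integer(closingRadius),
       connectivity = as.integer(connectivity))
}

#' Stack per-slice prediction vectors into an en-face map
#'
#' Row \code{i} of the map is the prediction vector of slice \code{i}.
#'
#' @param rows list of equal-length binary vectors in slice order, or a
#'   binary matrix.
#' @return a raw [ERMMap-class].
#' @export
buildMap <- function(rows) {
  if (is.list(rows)) {
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("ragged prediction vectors: lengths ", paste(unique(lens), collapse = ", "))
    rows <- do.call(rbind, rows)
  }
  new("ERMMap", grid = matrix(as.numeric(rows), nrow(rows), ncol(rows)),
      provenance = "raw")
}

#' Connected-component labeling with selectable connectivity
#'
#' Two-pass union-find labeling of the foreground of a binary mask under
#' 4- or 8-connectivity (8 counts diagonal adjacency, e.g. detections on
#' consecutive B-scans shifted by one column).
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), numbered
#'   consecutively from 1.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nextLab <- 0L
  for (cc in seq_len(W)) for (r in seq_len(H)) {
    if (mask[r, cc] == 0) next
    nbs <- integer(0)
    if (r > 1L && mask[r - 1L, cc] != 0) nbs <- c(nbs, lab[r - 1L, cc])
    if (cc > 1L && mask[r, cc - 1L] != 0) nbs <- c(nbs, lab[r, cc - 1L])
    if (connectivity == 8L && cc > 1L) {
      if (r > 1L && mask[r - 1L, cc - 1L] != 0) nbs <- c(nbs, lab[r - 1L, cc - 1L])
      if (r < H && mask[r + 1L, cc - 1L] != 0) nbs <- c(nbs, lab[r + 1L, cc - 1L])
    }
    if (length(nbs) == 0L) {
      nextLab <- nextLab + 1L
      parent[nextLab] <- nextLab
      lab[r, cc] <- nextLab
    } else {
      m <- min(nbs)
      lab[r, cc] <- m
      for (nb in nbs) {
        ra <- findRoot(nb); rb <- findRoot(m)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  if (nextLab > 0L) {
    roots <- vapply(seq_len(nextLab), findRoot, integer(1L))
    relab <- match(roots, sort(unique(roots)))
    pos <- lab > 0L
    lab[pos] <- relab[lab[pos]]
  }
  lab
}

# Binary closing with a disk, computed as if the map were embedded in an
# infinite background (zero padding wide enough that border effects cannot
# reach the map), so the operation is idempotent.
closeMask <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  pad <- 2L * radius
  kern <- EBImage::makeBrush(2L * radius + 1L, "disc")
  out <- EBImage::closing(padZero(mask, pad), kern)
  out[(pad + 1L):(pad + nrow(mask)), (pad + 1L):(pad + ncol(mask)), drop = FALSE]
}

#' Refine an en-face map morphologically
#'
#' Step 1: remove every connected component (under the configured
#' connectivity) whose pixel area is below \code{minArea}. Step 2: binary
#' closing with a disk of radius \code{closingRadius} on the surviving
#' mask, unifying small background gaps inside ERM regions. The operation
#' is idempotent: re-applying it with the same parameters leaves the map
#' unchanged.
#'
#' @param map an [ERMMap-class] or binary matrix.
#' @param params parameters from [postprocessParams()].
#' @return a refined [ERMMap-class].
#' @export
refineMap <- function(map, params = postprocessParams()) {
  grid <- asMapMatrix(map)
  if (params$minArea > 0L && any(grid == 1)) {
    lab <- labelComponents(grid, params$connectivity)
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= params$minArea)
    grid <- matrix(as.numeric(lab %in% keep), nrow(grid), ncol(grid))
  }
  grid <- closeMask(grid, params$closingRadius)
  new("ERMMap", grid = grid, provenance = "refined")
}

#' Grid-search the post-processing parameters
#'
#' Exhaustively evaluates every (minArea, closingRadius) combination,
#' maximizing the mean Dice coefficient over the supplied volumes (volumes
#' whose ground truth has no positive pixels contribute no Dice and are
#' skipped). Ties prefer the smaller \code{minArea}, then the smaller
#' \code{closingRadius}.
#'
#' @param rawMaps list of raw [ERMMap-class] predictions.
#' @param truthMaps list of matching ground-truth maps.
#' @param minAreaGrid,closingRadiusGrid candidate values.
#' @param connectivity component connectivity (4 or 8).
#' @return the winning [postprocessParams()] list, with the searched grid
#'   and its mean-Dice scores attached as attribute \code{"scores"}.
#' @export
optimizePostprocess <- function(rawMaps, truthMaps,
                                minAreaGrid = c(0L, 10L, 25L, 50L, 100L, 200L),
                                closingRadiusGrid = c(0L, 1L, 2L, 3L, 5L, 7L),
                                connectivity = 8L) {
  stopifnot(length(rawMaps) == length(truthMaps), length(rawMaps) >= 1L)
  truthGrids <- lapply(truthMaps, asMapMatrix)
  hasPos <- vapply(truthGrids, function(g) any(g == 1), logical(1L))
  if (!any(hasPos))
    stop("Dice is undefined when every ground truth is all-negative; ",
         "select parameters by specificity instead")
  scores <- expand.grid(minArea = as.integer(minAreaGrid),
                        closingRadius = as.integer(closingRadiusGrid))
  scores <- scores[order(scores$minArea, scores$closingRadius), , drop = FALSE]
  scores$meanDice <- NA_real_
  best <- NULL; bestDice <- -Inf
  for (g in seq_len(nrow(scores))) {
    p <- postprocessParams(scores$minArea[g], scores$closingRadius[g],
                           connectivity)
    dices <- numeric(0)
    for (v in which(hasPos)) {
      ref <- refineMap(rawMaps[[v]], p)
      dices <- c(dices, computeMetrics(confusionCounts(ref, truthGrids[[v]]))$dice)
    }
    md <- mean(dices)
    scores$meanDice[g] <- md
    if (md > bestDice) { bestDice <- md; best <- p }   # grid is tie-ordered
  }
  attr(best, "scores") <- scores
  best
}
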