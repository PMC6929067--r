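#' Snake parameters for ILM segmentation
#'
#' The ILM is recovered with a Kass-style discrete active contour restricted
#' to vertical movement: one row value per image column, initialized at the
#' top of the B-scan (vitreous side) and evolved towards the strong
#' vitreous-to-retina edge. The discrete energy is
#' \deqn{E(v) = \sum_c \frac{\alpha}{2}(v_{c+1}-v_c)^2 +
#'              \frac{\beta}{2}(v_{c+1}-2v_c+v_{c-1})^2 -
#'              w_e G(v_c, c) - w_p v_c}
#' where \eqn{G} is the per-column normalized gradient magnitude of the
#' Gaussian-smoothed scan (the edge map) and \eqn{w_p} is a small constant
#' downward pressure that carries the contour across the featureless
#' vitreous until an edge captures it. Steps are semi-implicit in the
#' internal terms with backtracking step halving, so the energy is
#' non-increasing over iterations by construction.
#'
#' @param alpha elasticity (first-derivative) weight.
#' @param beta rigidity (second-derivative) weight.
#' @param gamma step size.
#' @param externalSigma Gaussian smoothing scale (px) of the edge map.
#' @param maxIters iteration cap.
#' @param convTol mean per-point movement (px) declaring convergence.
#' @param edgeWeight weight of the edge (external) energy term.
#' @param pressure constant downward force crossing the vitreous; must be
#'   small relative to \code{edgeWeight} times the edge slope or the contour
#'   punches through weak edges.
#' @return a named list of validated snake parameters.
#' @export
snakeParams <- function(alpha = 0.1, beta = 1, gamma = 0.2,
                        externalSigma = 2, maxIters = 600, convTol = 0.02,
                        edgeWeight = 50, pressure = 2.5) {
  stopifnot(alpha > 0, beta > 0, gamma > 0, externalSigma > 0,
            maxIters >= 1, convTol > 0, edgeWeight > 0, pressure >= 0)
  list(alpha = alpha, beta = beta, gamma = gamma,
       externalSigma = externalSigma, maxIters = as.integer(maxIters),
       convTol = convTol, edgeWeight = edgeWeight, pressure = pressure)
}

# Linear interpolation of a row-indexed map at fractional rows v (one per
# column).
interpRows <- function(map, v) {
  H <- nrow(map)
  f <- pmin(pmax(floor(v), 1), H - 1L)
  t <- pmin(pmax(v - f, 0), 1)
  cols <- seq_len(ncol(map))
  map[cbind(f, cols)] * (1 - t) + map[cbind(f + 1L, cols)] * t
}

# Pentadiagonal internal-energy matrix for an open, column-parameterized
# contour: A = alpha D1'D1 + beta D2'D2 (free ends).
snakeInternalMatrix <- function(w, alpha, beta) {
  D1 <- diff(diag(w))
  D2 <- diff(diag(w), differences = 2)
  alpha * crossprod(D1) + beta * crossprod(D2)
}

snakeEnergy <- function(v, G, alpha, beta, edgeWeight, pressure) {
  sum(alpha / 2 * diff(v)^2) + sum(beta / 2 * diff(v, differences = 2)^2) -
    edgeWeight * sum(interpRows(G, v)) - pressure * sum(v)
}

# Edge map: gradient magnitude of the Gaussian-smoothed scan, smoothed once
# more (noise regularization + wider capture range), then normalized per
# column so weak- and strong-contrast A-scans present comparable edges.
snakeEdgeMap <- function(scan, sigma) {
  k <- gaussianKernel(sigma, maxSide = min(dim(scan)))
  sm <- convolve2(scan, k)
  g <- sqrt(gradientY(sm)^2 + gradientX(sm)^2)
  g <- convolve2(g, k)
  colMax <- apply(g, 2L, max)
  if (max(colMax) < 1e-9)
    stop("no edge found: the scan has no vertical gradient structure")
  sweep(g, 2L, pmax(colMax, 1e-9), "/")
}

#' Segment the ILM surface in one B-scan
#'
#' Runs the vertical snake described in [snakeParams()] from the top of the
#' image and returns the converged per-column ILM row coordinates. The
#' result is deterministic (no randomness is involved).
#'
#' @param scan numeric matrix (a B-scan, intensities in \code{[0, 1]}, row 1
#'   = top of scan).
#' @param params parameters from [snakeParams()].
#' @return numeric vector of length \code{ncol(scan)} with the ILM row per
#'   column, with attributes \code{energy} (the per-iteration energy trace,
#'   non-increasing), \code{iterations} and \code{converged}.
#' @export
segmentILM <- function(scan, params = snakeParams()) {
  stopifnot(is.matrix(scan), nrow(scan) > 1L, ncol(scan) > 2L)
  G <- snakeEdgeMap(scan, params$externalSigma)
  H <- nrow(scan); W <- ncol(scan)
  A <- snakeInternalMatrix(W, params$alpha, params$beta)
  stepCache <- new.env(parent = emptyenv())
  stepMatrix <- function(g) {
    key <- format(g, digits = 12)
    if (is.null(stepCache[[key]]))
      stepCache[[key]] <- solve(diag(W) + g * A)
    stepCache[[key]]
  }
  dGdy <- gradientY(G)

  v <- rep(1, W)
  eTrace <- numeric(0)
  e <- snakeEnergy(v, G, params$alpha, params$beta,
                   params$edgeWeight, params$pressure)
  converged <- FALSE
  iter <- 0L
  while (iter < params$maxIters) {
    iter <- iter + 1L
    force <- params$edgeWeight * interpRows(dGdy, v) + params$pressure
    g <- params$gamma
    accepted <- FALSE
    for (halving in 0:25) {
      vNew <- pmin(pmax(as.vector(stepMatrix(g) %*% (v + g * force)), 1), H)
      eNew <- snakeEnergy(vNew, G, params$alpha, params$beta,
                          params$edgeWeight, params$pressure)
      if (eNew <= e + 1e-12) { accepted <- TRUE; break }
      g <- g / 2
    }
    if (!accepted) { converged <- TRUE; break }     # local minimum
    move <- mean(abs(vNew - v))
    v <- vNew; e <- eNew
    eTrace <- c(eTrace, e)
    if (move < params$convTol) { converged <- TRUE; break }
  }
  structure(v, energy = eTrace, iterations = iter, converged = converged)
}

#' Segment the ILM in every slice of a volume
#'
#' @param volume an [OCTVolume-class].
#' @param params parameters from [snakeParams()].
#' @return numeric matrix, \code{nSlices x width}, of ILM row coordinates.
#' @export
segmentVolume <- function(volume, params = snakeParams()) {
  stopifnot(is(volume, "OCTVolume"))
  out <- matrix(0, nSlices(volume), scanWidth(volume))
  for (s in seq_len(nSlices(volume)))
    out[s, ] <- as.vector(segmentILM(volume@slices[[s]], params))
  out
}
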