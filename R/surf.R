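# SURF (Spatial Uniform ReliefF) feature ranking.
#
# ReliefF scores a feature by contrasting its value differences between an
# instance and its nearest hits (same class) and misses (other class), but
# requires choosing the neighbor count k. SURF replaces k with a global
# threshold: the mean Euclidean distance over all unordered instance pairs;
# every instance closer than the threshold is a neighbor. All instances are
# used (no sampling), so the ranking is deterministic and invariant to
# sample order.

#' Rank features by SURF relevance
#'
#' Features are min-max scaled to \code{[0, 1]} over the sample set before
#' distance computation (constant features scale to 0 and receive weight
#' exactly 0). With \eqn{T} the mean pairwise Euclidean distance, the
#' neighbors of instance \eqn{i} are all \eqn{j \neq i} with
#' \eqn{d(i,j) < T}. Each miss neighbor adds
#' \eqn{|x_{if} - x_{jf}| / (n\,m_i)} to feature \eqn{f}'s weight and each
#' hit neighbor subtracts \eqn{|x_{if} - x_{jf}| / (n\,h_i)}, where
#' \eqn{m_i}/\eqn{h_i} are instance \eqn{i}'s miss/hit neighbor counts and
#' \eqn{n} the number of instances.
#'
#' @param X numeric matrix, samples in rows, features in columns; no
#'   missing values.
#' @param y binary labels (0/1), one per row of \code{X}.
#' @param featureNames optional feature names (defaults to
#'   \code{colnames(X)}).
#' @return a [FeatureRanking-class]; ranking ties are broken by ascending
#'   feature index.
#' @export
surfRank <- function(X, y, featureNames = colnames(X)) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (anyNA(X)) stop("X must not contain missing values")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  if (length(unique(y)) < 2L)
    stop("ReliefF-family weights undefined without both classes")
  if (is.null(featureNames)) featureNames <- sprintf("f%03d", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)

  lo <- apply(X, 2L, min)
  rngs <- apply(X, 2L, max) - lo
  rngs[rngs < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, lo), 2L, rngs, "/")

  D <- as.matrix(stats::dist(Xs))
  thr <- mean(D[upper.tri(D)])
  W <- numeric(p)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < thr)
    nb <- nb[nb != i]
    if (length(nb) == 0L) next
    hits <- nb[y[nb] == y[i]]
    miss <- nb[y[nb] != y[i]]
    if (length(miss) > 0L) {
      dm <- abs(Xs[miss, , drop = FALSE] -
                  matrix(Xs[i, ], length(miss), p, byrow = TRUE))
      W <- W + .colSums(dm, length(miss), p) / (n * length(miss))
    }
    if (length(hits) > 0L) {
      dh <- abs(Xs[hits, , drop = FALSE] -
                  matrix(Xs[i, ], length(hits), p, byrow = TRUE))
      W <- W - .colSums(dh, length(hits), p) / (n * length(hits))
    }
  }
  new("FeatureRanking", weights = W,
      order = as.integer(order(-W, seq_len(p))),
      featureNames = as.character(featureNames))
}

#' Select the top-k ranked features
#'
#' Returns the first \code{k} indices of the ranking order; by
#' construction \code{selectTop(r, k)} is a prefix of
#' \code{selectTop(r, k + 1)}.
#'
#' @param ranking a [FeatureRanking-class].
#' @param k number of features to keep, \code{1 <= k <= n_features}.
#' @return integer vector of feature indices, most relevant first.
#' @export
selectTop <- function(ranking, k) {
  stopifnot(is(ranking, "FeatureRanking"))
  n <- length(ranking@weights)
  if (k < 1L || k > n)
    stop("k must be in [1, ", n, "], got ", k)
  ranking@order[seq_len(as.integer(k))]
}

#' Export a ranking as a data.frame
#'
#' @param ranking a [FeatureRanking-class].
#' @return data.frame with \code{rank}, \code{feature}, \code{weight}.
#' @export
rankingTable <- function(ranking) {
  stopifnot(is(ranking, "FeatureRanking"))
  data.frame(rank = seq_along(ranking@order),
             feature = ranking@featureNames[ranking@order],
             weight = ranking@weights[ranking@order])
}
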