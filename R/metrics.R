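# Map-level evaluation: confusion counts and the sensitivity /
# specificity / Dice / Jaccard coefficients
#   sensitivity = TP / (TP + FN)        specificity = TN / (TN + FP)
#   Dice = 2 TP / (2 TP + FP + FN)      Jaccard = TP / (TP + FP + FN)
# computed per en-face map pixel. For volumes without any true ERM
# (TP + FN = 0) sensitivity, Dice and Jaccard are undefined and reported
# as NA; only specificity is meaningful there.

#' Pixel-wise confusion counts between two binary maps
#'
#' @param pred predicted [ERMMap-class] or binary matrix.
#' @param truth ground-truth map of identical shape.
#' @return named list with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusionCounts <- function(pred, truth) {
  p <- asMapMatrix(pred); t <- asMapMatrix(truth)
  if (!all(dim(p) == dim(t)))
    stop("shape mismatch: pred is ", paste(dim(p), collapse = "x"),
         ", truth is ", paste(dim(t), collapse = "x"))
  list(TP = sum(p == 1 & t == 1), FP = sum(p == 1 & t == 0),
       TN = sum(p == 0 & t == 0), FN = sum(p == 0 & t == 1))
}

#' Metrics from confusion counts
#'
#' Exact formulas; a metric whose denominator is zero is reported as
#' \code{NA}. In addition, sensitivity, Dice and Jaccard are \code{NA}
#' whenever \code{TP + FN == 0} (no true positives exist, as in ERM-free
#' volumes).
#'
#' @param cc confusion counts from [confusionCounts()].
#' @param volumeID,stage optional labels carried into the report.
#' @return data.frame row with \code{sensitivity}, \code{specificity},
#'   \code{dice}, \code{jaccard} (plus any labels).
#' @export
computeMetrics <- function(cc, volumeID = NA_character_, stage = NA_character_) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  noPos <- (cc$TP + cc$FN) == 0
  data.frame(
    volumeID = volumeID, stage = stage,
    sensitivity = if (noPos) NA_real_ else ratio(cc$TP, cc$TP + cc$FN),
    specificity = ratio(cc$TN, cc$TN + cc$FP),
    dice = if (noPos) NA_real_ else ratio(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN),
    jaccard = if (noPos) NA_real_ else ratio(cc$TP, cc$TP + cc$FP + cc$FN),
    stringsAsFactors = FALSE)
}

#' Aggregate per-volume metric reports by patient class and stage
#'
#' Arithmetic mean and sample (n-1) standard deviation across volumes;
#' undefined (\code{NA}) metrics are excluded from aggregation, so ERM-free
#' volume groups aggregate only specificity. Groups with a single volume
#' report sd 0 and are flagged by \code{n}.
#'
#' @param reports data.frame of [computeMetrics()] rows with an added
#'   \code{class} column (e.g. \code{"ERM"} / \code{"non-ERM"}).
#' @return data.frame with one row per class x stage x metric:
#'   \code{mean}, \code{sd}, \code{n}.
#' @export
aggregateMetrics <- function(reports) {
  stopifnot(all(c("class", "stage") %in% names(reports)))
  metrics <- c("sensitivity", "specificity", "dice", "jaccard")
  out <- list()
  for (cl in unique(reports$class)) for (st in unique(reports$stage)) {
    sub <- reports[reports$class == cl & reports$stage == st, , drop = FALSE]
    if (nrow(sub) == 0L) { warning("empty class/stage group: ", cl, "/", st); next }
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        class = cl, stage = st, metric = m, mean = mean(v),
        sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Dice to Jaccard conversion
#'
#' For any single confusion matrix the two overlap coefficients are linked
#' by \eqn{J = D / (2 - D)}.
#'
#' @param dice Dice coefficient(s) in \code{[0, 1]}.
#' @return the corresponding Jaccard coefficient(s).
#' @export
diceToJaccard <- function(dice) dice / (2 - dice)
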