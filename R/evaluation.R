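#' Confusion counts at a threshold
#'
#' Binarizes probabilities at `threshold` (ties predict positive:
#' `p >= threshold`) and counts true/false positives/negatives.
#'
#' @param preds scored predictions: data.frame with columns `y` (0/1) and
#'   `p` (probability).
#' @param threshold decision threshold, default 0.5.
#' @return A [ConfusionCounts-class].
#' @examples
#' confusion(data.frame(y = c(1, 0), p = c(0.9, 0.2)))
#' @export
confusion <- function(preds, threshold = 0.5) {
  if (nrow(preds) == 0) stop("no scored records", call. = FALSE)
  stopifnot(all(preds$y %in% c(0, 1)), all(preds$p >= 0 & preds$p <= 1))
  yhat <- as.numeric(preds$p >= threshold)
  new("ConfusionCounts",
      TP = sum(yhat == 1 & preds$y == 1), TN = sum(yhat == 0 & preds$y == 0),
      FP = sum(yhat == 1 & preds$y == 0), FN = sum(yhat == 0 & preds$y == 1),
      threshold = threshold)
}

countsTotal <- function(cc) cc@TP + cc@TN + cc@FP + cc@FN

# Ratio that flags zero denominators instead of silently returning 0.
safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Threshold metrics from confusion counts
#'
#' Precision, recall, accuracy and F1. A metric whose denominator is zero
#' is reported as `NA` and listed in the `undefined` attribute, never
#' silently zero.
#'
#' @param cc a [ConfusionCounts-class].
#' @return Named list `precision, recall, accuracy, f1` with an
#'   `undefined` character attribute.
#' @export
basicMetrics <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"))
  precision <- safeRatio(cc@TP, cc@TP + cc@FP)
  recall <- safeRatio(cc@TP, cc@TP + cc@FN)
  accuracy <- safeRatio(cc@TP + cc@TN, countsTotal(cc))
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- list(precision = precision, recall = recall, accuracy = accuracy,
              f1 = f1)
  attr(out, "undefined") <- names(out)[vapply(out, is.na, TRUE)]
  out
}

#' Cohen's kappa for binary classification
#'
#' Chance-corrected agreement,
#' \deqn{\kappa = \frac{2(TP \cdot TN - FN \cdot FP)}
#'   {(TP+FP)(FP+TN) + (TP+FN)(FN+TN)},}
#' algebraically identical to the \eqn{(P_0 - P_e)/(1 - P_e)} form. Ranges
#' from -1 (complete disagreement) through 0 (chance) to 1 (perfect).
#'
#' @param cc a [ConfusionCounts-class].
#' @return Kappa, or `NA` (flagged via attribute) when the denominator is
#'   zero.
#' @export
cohenKappa <- function(cc) {
  stopifnot(is(cc, "ConfusionCounts"), countsTotal(cc) > 0)
  den <- (cc@TP + cc@FP) * (cc@FP + cc@TN) + (cc@TP + cc@FN) * (cc@FN + cc@TN)
  k <- safeRatio(2 * (cc@TP * cc@TN - cc@FN * cc@FP), den)
  attr(k, "undefined") <- is.na(k)
  k
}

#' ROC curve and area under it
#'
#' The AUC equals the probability that a random positive outranks a random
#' negative, with ties counted half (computed from midranks, so invariant
#' under strictly monotone score transforms). The curve sweeps all score
#' thresholds.
#'
#' @param preds scored predictions with columns `y` and `p`.
#' @return List with `auc` and `curve` (data.frame of threshold, fpr, tpr).
#' @export
rocAuc <- function(preds) {
  y <- preds$y; p <- preds$p
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present for ROC analysis", call. = FALSE)
  r <- rank(p, ties.method = "average")
  auc <- (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(p >= t & y == 0) / nNeg, 1),
    tpr = vapply(thr, function(t) sum(p >= t & y == 1) / nPos, 1))
  list(auc = auc, curve = curve)
}

#' Aggregate chunk predictions over consecutive groups
#'
#' Combines `chunksPerGroup` consecutive chunks of the same video into one
#' record whose score is the mean of the member probabilities (rank
#' equivalent to summing them, and bounded in [0, 1]); the label is
#' inherited. Grouping never crosses video boundaries, requires contiguous
#' chunk indices within each video, and drops trailing partial groups. At
#' 1000 fps with 40-frame chunks, 25 chunks form one second of recording.
#'
#' @param preds scored chunk predictions (columns `videoId, chunkIndex, y,
#'   p`).
#' @param chunksPerGroup chunks per aggregated record (>= 1).
#' @return Aggregated scored predictions with columns `videoId, groupIndex,
#'   y, p, nChunks` (plus inherited metadata columns).
#' @export
aggregateOverSecond <- function(preds, chunksPerGroup = 25L) {
  if (chunksPerGroup < 1) stop("chunksPerGroup must be >= 1", call. = FALSE)
  out <- lapply(split(preds, preds$videoId), function(v) {
    v <- v[order(v$chunkIndex), , drop = FALSE]
    if (!all(diff(v$chunkIndex) == 1))
      stop("chunk indices must be contiguous within each video",
           call. = FALSE)
    if (length(unique(v$y)) != 1)
      stop("labels differ within one video", call. = FALSE)
    grp <- (v$chunkIndex - v$chunkIndex[1]) %/% chunksPerGroup
    full <- as.vector(table(grp)) == chunksPerGroup
    keep <- grp %in% (unique(grp)[full])
    v <- v[keep, , drop = FALSE]; grp <- grp[keep]
    if (!nrow(v)) return(NULL)
    agg <- data.frame(videoId = v$videoId[1], groupIndex = sort(unique(grp)),
                      y = v$y[1],
                      p = as.vector(tapply(v$p, grp, mean)),
                      nChunks = as.integer(chunksPerGroup))
    for (col in intersect(c("subject", "session", "region", "classLabel"),
                          names(v)))
      agg[[col]] <- v[[col]][1]
    agg
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Average the predictions of several models
#'
#' Per-chunk arithmetic mean of the member probabilities: the split-model
#' ensemble used to score held-out subjects.
#'
#' @param models non-empty list of [ConvLSTMModel-class] objects with
#'   identical input geometry.
#' @param chunks a [ChunkSet-class].
#' @param positiveClass label mapped to `y = 1`.
#' @return Scored predictions in the [predictChunks()] format.
#' @export
ensembleAverage <- function(models, chunks, positiveClass = "clear") {
  if (length(models) == 0) stop("empty model list", call. = FALSE)
  preds <- lapply(models, predictChunks, chunks = chunks,
                  positiveClass = positiveClass)
  out <- preds[[1]]
  if (length(preds) > 1) {
    pm <- vapply(preds, function(d) d$p, numeric(nrow(out)))
    out$p <- rowMeans(pm)
  }
  out
}

#' Accuracy-maximizing decision threshold
#'
#' Scans the midpoints between consecutive unique scores (plus the
#' extremes) and returns the threshold with the highest accuracy under the
#' `p >= threshold` rule. Decision thresholds drift across subjects and
#' recording sessions (the score distribution moves even when the ranking
#' is preserved), so threshold calibration is exposed as an explicit,
#' separate step: calibrate on held-out data of the target session, or
#' report threshold-free AUC.
#'
#' @param preds scored predictions with columns `y` and `p`.
#' @return The calibrated threshold.
#' @export
bestThreshold <- function(preds) {
  ps <- sort(unique(preds$p))
  cand <- unique(c(0, ps, (ps[-1] + ps[-length(ps)]) / 2, 1))
  acc <- vapply(cand, function(t) mean((preds$p >= t) == preds$y), 1)
  cand[which.max(acc)]
}

#' Full metric report
#'
#' Confusion-based metrics at `threshold` plus ROC-AUC (when both classes
#' are present).
#'
#' @param preds scored predictions with columns `y` and `p`.
#' @param threshold decision threshold.
#' @return A [MetricReport-class].
#' @export
metricReport <- function(preds, threshold = 0.5) {
  cc <- confusion(preds, threshold)
  bm <- basicMetrics(cc)
  kp <- cohenKappa(cc)
  auc <- if (length(unique(preds$y)) == 2) rocAuc(preds)$auc else NA_real_
  undef <- attr(bm, "undefined")
  if (isTRUE(attr(kp, "undefined"))) undef <- c(undef, "kappa")
  new("MetricReport", precision = bm$precision, recall = bm$recall,
      accuracy = bm$accuracy, f1 = bm$f1, kappa = as.numeric(kp), auc = auc,
      counts = cc, n = as.integer(nrow(preds)), undefined = undef)
}
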