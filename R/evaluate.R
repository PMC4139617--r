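# Counting agreement against ground truth.

#' Evaluate predicted cells against ground truth
#'
#' Greedy one-to-one matching by descending pixel overlap. A predicted
#' cell matches a ground-truth cell when their intersection-over-union is
#' at least \code{iouThreshold}, or, failing that, when the predicted
#' centroid falls inside the truth region. Matched pairs are true
#' positives; unmatched predictions are false positives (over-segmentation)
#' and unmatched truth cells false negatives (under-segmentation).
#'
#' @param predicted list of predicted cell pixel matrices
#'   (\code{\link{predictedCells}}), or \code{NULL} when using raw counts.
#' @param truth list of ground-truth cell pixel matrices.
#' @param iouThreshold minimum IoU for a match (default 0.5).
#' @return A \linkS4class{CountReport}.
#' @examples
#' px <- discPixels(c(20, 20), 8)
#' evaluateCounts(list(px), list(px))   # perfect: F = 100
#' @export
evaluateCounts <- function(predicted, truth, iouThreshold = 0.5) {
  np <- length(predicted); nt <- length(truth)
  if (np == 0L && nt == 0L)
    return(countReport(0L, 0L, 0L))
  if (np == 0L) return(countReport(0L, 0L, nt))
  if (nt == 0L) return(countReport(0L, np, 0L))
  keyed <- function(p) paste(p[, 1L], p[, 2L])
  pk <- lapply(predicted, keyed); tk <- lapply(truth, keyed)
  # candidate overlaps
  ov <- NULL
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    inter <- sum(pk[[i]] %in% tk[[j]])
    if (inter > 0L)
      ov <- rbind(ov, c(i, j, inter))
  }
  tp <- 0L
  if (!is.null(ov)) {
    ov <- ov[order(-ov[, 3L], ov[, 1L], ov[, 2L]), , drop = FALSE]
    usedP <- logical(np); usedT <- logical(nt)
    for (r in seq_len(nrow(ov))) {
      i <- ov[r, 1L]; j <- ov[r, 2L]; inter <- ov[r, 3L]
      if (usedP[i] || usedT[j]) next
      iou <- inter / (length(pk[[i]]) + length(tk[[j]]) - inter)
      ok <- iou >= iouThreshold
      if (!ok) {
        cen <- round(colMeans(predicted[[i]]))
        ok <- paste(cen[1L], cen[2L]) %in% tk[[j]]
      }
      if (ok) { usedP[i] <- TRUE; usedT[j] <- TRUE; tp <- tp + 1L }
    }
  }
  countReport(tp, np - tp, nt - tp)
}

#' Build a counting report from raw TP/FP/FN
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F = 2PR/(P+R), reported as percentages. An empty comparison (all three
#' zero) is perfect agreement by definition.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return A \linkS4class{CountReport}.
#' @examples
#' countReport(9, 1, 1)   # 90% across the board
#' @export
countReport <- function(tp, fp, fn) {
  tp <- as.integer(tp); fp <- as.integer(fp); fn <- as.integer(fn)
  if (tp == 0L && fp == 0L && fn == 0L) {
    p <- r <- f <- 100
  } else {
    p <- if (tp + fp > 0L) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0L) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  new("CountReport", tp = tp, fp = fp, fn = fn,
      precision = p, recall = r, fmeasure = f)
}
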