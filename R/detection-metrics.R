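# Object-detection evaluation: IOU, greedy matching, AP, mAP, F1.

#' Intersection over union of centre-format boxes
#'
#' Boxes are half-open pixel rectangles `[cx - w/2, cx + w/2) x
#' [cy - h/2, cy + h/2)`. Vectorised over equal-length inputs (either side
#' may be length 1).
#'
#' @param cx1,cy1,w1,h1 first box (or vector of boxes).
#' @param cx2,cy2,w2,h2 second box (or vector of boxes).
#' @return IOU values in `[0, 1]`; 0 for disjoint boxes.
#' @export
#' @examples
#' boxIoU(5, 5, 10, 10, 10, 5, 10, 10)  # 50 / 150 = 1/3
boxIoU <- function(cx1, cy1, w1, h1, cx2, cy2, w2, h2) {
  ix <- pmax(0, pmin(cx1 + w1 / 2, cx2 + w2 / 2) -
                pmax(cx1 - w1 / 2, cx2 - w2 / 2))
  iy <- pmax(0, pmin(cy1 + h1 / 2, cy2 + h2 / 2) -
                pmax(cy1 - h1 / 2, cy2 - h2 / 2))
  inter <- ix * iy
  union <- w1 * h1 + w2 * h2 - inter
  ifelse(union > 0, inter / union, 0)
}

#' Greedy TP/FP matching of detections against ground truth
#'
#' Detections are processed in descending confidence; a detection is a true
#' positive if it overlaps an as-yet-unmatched ground-truth box of the same
#' class with IOU at or above the threshold (matched greedily to the
#' highest-IOU such box), otherwise a false positive. Each ground-truth box
#' matches at most once; leftover ground truths are false negatives. A
#' correctly placed box of the wrong class is an FP and leaves its ground
#' truth to count as an FN.
#'
#' @param preds data frame with columns `class, cx, cy, w, h, mu`.
#' @param gts data frame with columns `class, cx, cy, w, h`.
#' @param iouThreshold matching threshold in (0, 1], default 0.5.
#' @return list with `labels` (the predictions in descending-`mu` order with
#'   a logical `tp` column), `fn` (count of unmatched ground truths).
#' @export
matchDetections <- function(preds, gts, iouThreshold = 0.5) {
  stopifnot(iouThreshold > 0, iouThreshold <= 1)
  preds <- preds[order(-preds$mu), , drop = FALSE]
  rownames(preds) <- NULL
  matched <- rep(FALSE, nrow(gts))
  tp <- rep(FALSE, nrow(preds))
  for (i in seq_len(nrow(preds))) {
    cand <- which(!matched & gts$class == preds$class[i])
    if (!length(cand)) next
    ious <- boxIoU(preds$cx[i], preds$cy[i], preds$w[i], preds$h[i],
                   gts$cx[cand], gts$cy[cand], gts$w[cand], gts$h[cand])
    jbest <- which.max(ious)
    if (ious[jbest] >= iouThreshold) {
      matched[cand[jbest]] <- TRUE
      tp[i] <- TRUE
    }
  }
  preds$tp <- tp
  list(labels = preds, fn = sum(!matched))
}

#' All-point interpolated average precision
#'
#' Given TP/FP flags ordered by descending confidence and the ground-truth
#' count, computes `AP = sum_n (R_{n+1} - R_n) * max_{R' >= R_{n+1}} P(R')`,
#' interpolating precision through all recall points.
#'
#' @param tp logical TP flags sorted by descending confidence.
#' @param nGt number of ground-truth instances of the class.
#' @return AP in `[0, 1]`; 0 when `nGt` is 0 (spurious detections of an
#'   absent class score zero), and 0 when there are no detections of a
#'   present class.
#' @export
#' @examples
#' averagePrecision(c(TRUE, FALSE), 1)  # 1.0
#' averagePrecision(c(FALSE, TRUE), 1)  # 0.5
averagePrecision <- function(tp, nGt) {
  if (nGt == 0 || !length(tp)) return(0)
  cumTP <- cumsum(tp)
  recall <- cumTP / nGt
  precision <- cumTP / seq_along(tp)
  # interpolated precision: running max from the right
  pInterp <- rev(cummax(rev(precision)))
  r <- c(0, recall)
  sum((r[-1] - r[-length(r)]) * pInterp)
}

#' Evaluate detections against ground truth
#'
#' Aggregates one or many scenes: detections are matched per scene with
#' [matchDetections()], then pooled per class across scenes (sorted by
#' descending confidence) for the AP computation. Classes appearing in the
#' ground truth or in the detections are reported; a class with detections
#' but no ground truth contributes AP 0 to the mean. Micro precision,
#' recall and F1 are computed from the pooled TP/FP/FN counts.
#'
#' @param preds data frame `class, cx, cy, w, h, mu`, or a list of them
#'   (one per scene).
#' @param gts data frame `class, cx, cy, w, h`, or a list parallel to
#'   `preds`.
#' @param iouThreshold matching threshold, default 0.5.
#' @return a [MatchReport-class].
#' @export
evaluateDetections <- function(preds, gts, iouThreshold = 0.5) {
  if (is.data.frame(preds)) preds <- list(preds)
  if (is.data.frame(gts)) gts <- list(gts)
  if (length(preds) != length(gts)) {
    stop("preds and gts must pair up scene by scene")
  }
  labels <- vector("list", length(preds))
  fnByClass <- list()
  gtCount <- list()
  for (i in seq_along(preds)) {
    m <- matchDetections(preds[[i]], gts[[i]], iouThreshold)
    labels[[i]] <- m$labels
    for (cl in unique(as.character(gts[[i]]$class))) {
      gtCount[[cl]] <- (gtCount[[cl]] %||% 0) +
        sum(gts[[i]]$class == cl)
    }
  }
  pooled <- do.call(rbind, labels)
  classes <- sort(unique(c(names(gtCount),
                           as.character(pooled$class))))
  rows <- lapply(classes, function(cl) {
    sub <- pooled[pooled$class == cl, , drop = FALSE]
    sub <- sub[order(-sub$mu), , drop = FALSE]
    nGt <- gtCount[[cl]] %||% 0
    tp <- sum(sub$tp)
    fp <- sum(!sub$tp)
    data.frame(class = cl, instances = nGt, tp = tp, fp = fp,
               precision = if (tp + fp > 0) tp / (tp + fp) else 0,
               recall = if (nGt > 0) tp / nGt else 0,
               ap = averagePrecision(sub$tp, nGt),
               stringsAsFactors = FALSE)
  })
  perClass <- do.call(rbind, rows)
  TP <- sum(perClass$tp)
  FP <- sum(perClass$fp)
  FN <- sum(perClass$instances) - TP
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  new("MatchReport", perClass = perClass,
      micro = c(tp = TP, fp = FP, fn = FN, precision = P, recall = R,
                f1 = F1),
      mAP = mean(perClass$ap))
}
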