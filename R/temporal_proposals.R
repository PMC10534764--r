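## Shared anchor machinery for the segment detectors: anchor generation,
## center/length offset transforms, temporal IoU, target assignment, greedy
## NMS and the joint classification + regression loss.

#' Generate uniformly spaced temporal anchor segments
#'
#' Anchors are placed at every feature-map position (center of position j is
#' (j + 0.5) * stride frames, j = 0..n-1), one per scale, so the anchor
#' count is \code{nPositions * length(scales)}.
#'
#' @param nPositions number of feature-map positions.
#' @param scales anchor lengths in frames. The depth detector's default is
#'   c(2, 4, 5, 6, 8, 9, 10, 12, 14, 16); the skeleton detector uses
#'   c(50, 100, 200, 400).
#' @param stride frames between adjacent positions.
#' @return data.frame with columns \code{center}, \code{length},
#'   \code{position}, \code{scale}.
#' @examples
#' generateAnchors(2, scales = 2, stride = 8)  # centers 4 and 12
#' @export
generateAnchors <- function(nPositions, scales, stride) {
  stopifnot(nPositions >= 1, all(scales > 0), stride > 0)
  pos <- rep(seq_len(nPositions) - 1L, each = length(scales))
  sc <- rep(seq_along(scales), times = nPositions)
  data.frame(center = (pos + 0.5) * stride,
             length = scales[sc], position = pos, scale = scales[sc])
}

#' Anchor offset transforms
#'
#' Encodes a segment (center x, length w) relative to an anchor
#' (x_a, w_a) as t_x = (x - x_a) / w_a and t_w = log(w / w_a); decoding is
#' the exact inverse: x = x_a + t_x * w_a, w = w_a * exp(t_w).
#'
#' @param x,w segment center and length (frames), w > 0.
#' @param tx,tw encoded offsets.
#' @param xa,wa anchor center and length, wa > 0.
#' @return \code{encodeOffsets}: data.frame(tx, tw); \code{decodeOffsets}:
#'   data.frame(center, length). All arguments recycle.
#' @examples
#' encodeOffsets(10, 8, 8, 4)   # tx = 0.5, tw = log(2)
#' @export
encodeOffsets <- function(x, w, xa, wa) {
  if (any(w <= 0) || any(wa <= 0))
    stop("segment and anchor lengths must be positive")
  data.frame(tx = (x - xa) / wa, tw = log(w / wa))
}

#' @rdname encodeOffsets
#' @export
decodeOffsets <- function(tx, tw, xa, wa) {
  if (any(wa <= 0)) stop("anchor lengths must be positive")
  data.frame(center = xa + tx * wa, length = wa * exp(tw))
}

#' Temporal intersection over union of half-open frame intervals
#'
#' @param aStart,aEnd,bStart,bEnd interval bounds (vectors recycle).
#' @return IoU in [0, 1]; 1 iff the intervals are equal, 0 when disjoint.
#' @examples
#' temporalIoU(0, 10, 5, 15)  # 5 / 15
#' @export
temporalIoU <- function(aStart, aEnd, bStart, bEnd) {
  inter <- pmax(0, pmin(aEnd, bEnd) - pmax(aStart, bStart))
  union <- (aEnd - aStart) + (bEnd - bStart) - inter
  ifelse(union > 0, inter / union, 0)
}

segIoUMatrix <- function(s1, e1, s2, e2) {
  outer(seq_along(s1), seq_along(s2), function(i, j)
    temporalIoU(s1[i], e1[i], s2[j], e2[j]))
}

#' Assign classification and regression targets to anchors
#'
#' An anchor is positive (label 1) when its best IoU against the ground
#' truth reaches \code{posThr}, negative (label 0) below \code{negThr}, and
#' ignored (NA) in between. In addition, the best-matching anchor of every
#' ground-truth segment is forced positive, so no ground truth goes
#' unassigned. Positives receive offset targets towards their best-IoU
#' ground truth; they also carry that ground truth's class label for the
#' refinement stage.
#'
#' @param anchors data.frame from \code{\link{generateAnchors}}.
#' @param gt an \linkS4class{ActionSegments} of ground-truth action
#'   instances (background segments are ignored).
#' @param posThr,negThr IoU thresholds (defaults 0.7 / 0.3).
#' @return data.frame: columns \code{label} (1/0/NA), \code{tx}, \code{tw}
#'   (NA for non-positives), \code{gtIndex}, \code{gtLabel}.
#' @export
assignAnchorTargets <- function(anchors, gt, posThr = 0.7, negThr = 0.3) {
  df <- segmentTable(gt)
  df <- df[df$label != backgroundLabel(), , drop = FALSE]
  nA <- nrow(anchors)
  out <- data.frame(label = rep(0, nA), tx = NA_real_, tw = NA_real_,
                    gtIndex = NA_integer_, gtLabel = NA_character_)
  if (!nrow(df)) return(out)
  aS <- anchors$center - anchors$length / 2
  aE <- anchors$center + anchors$length / 2
  iou <- segIoUMatrix(aS, aE, df$start, df$end)
  best <- max.col(iou, ties.method = "first")
  bestIoU <- iou[cbind(seq_len(nA), best)]
  out$label <- ifelse(bestIoU >= posThr, 1,
                      ifelse(bestIoU < negThr, 0, NA))
  ## force-match the best anchor of every ground truth
  for (g in seq_len(nrow(df))) {
    a <- which.max(iou[, g])
    if (iou[a, g] > 0) {
      out$label[a] <- 1
      best[a] <- g
    }
  }
  pos <- which(out$label == 1)
  if (length(pos)) {
    gx <- (df$start[best[pos]] + df$end[best[pos]]) / 2
    gw <- df$end[best[pos]] - df$start[best[pos]]
    enc <- encodeOffsets(gx, gw, anchors$center[pos], anchors$length[pos])
    out$tx[pos] <- enc$tx
    out$tw[pos] <- enc$tw
    out$gtIndex[pos] <- best[pos]
    out$gtLabel[pos] <- df$label[best[pos]]
  }
  out
}

#' Greedy temporal non-maximum suppression
#'
#' Sorts segments by descending score (ties broken by earlier start, then
#' shorter length, so the output is deterministic and independent of input
#' order), keeps the best, and discards any remaining segment whose IoU
#' with a kept one reaches \code{iouThr}. Scores are passed through
#' unchanged.
#'
#' @param segments an \linkS4class{ActionSegments}.
#' @param iouThr suppression threshold (kept segments have pairwise IoU
#'   strictly below it).
#' @return an \linkS4class{ActionSegments} of survivors, in score order.
#' @export
nmsSegments <- function(segments, iouThr = 0.7) {
  df <- segmentTable(segments)
  if (nrow(df) <= 1L) return(segments)
  ord <- order(-df$score, df$start, df$end - df$start)
  df <- df[ord, , drop = FALSE]
  keep <- logical(nrow(df))
  alive <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    if (i < nrow(df)) {
      rest <- which(alive & seq_len(nrow(df)) > i)
      if (length(rest)) {
        iou <- temporalIoU(df$start[i], df$end[i], df$start[rest],
                           df$end[rest])
        alive[rest[iou >= iouThr]] <- FALSE
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  ActionSegments(df$start, df$end, df$label, df$score, df$personId)
}

smoothL1 <- function(u) ifelse(abs(u) < 1, 0.5 * u^2, abs(u) - 0.5)

#' Joint classification + regression loss for anchor training
#'
#' Mean softmax cross-entropy over the classification batch plus
#' lambda / N_reg times the smooth-L1 regression penalty, the latter summed
#' only over positive anchors (a_i* = 1): negatives contribute no
#' regression term regardless of their predicted offsets. Zero exactly at
#' perfect prediction.
#'
#' @param probs N x C matrix of predicted class probabilities (rows sum
#'   to 1).
#' @param classTargets integer vector of true class indices (1-based into
#'   the columns of \code{probs}).
#' @param anchorLabels 0/1 vector: a_i*, which anchors are positive.
#' @param tPred,tTarget N x 2 matrices of predicted / target (tx, tw)
#'   offsets (rows for non-positive anchors may be NA).
#' @param lambda trade-off weight (default 1).
#' @param nReg regression normalizer N_reg (default: number of anchors).
#' @param eps probability floor inside the log.
#' @return scalar loss.
#' @examples
#' p <- rbind(c(1, 0), c(0, 1))
#' jointLoss(p, c(1, 2), c(0, 0), matrix(0, 2, 2), matrix(0, 2, 2))  # 0
#' @export
jointLoss <- function(probs, classTargets, anchorLabels, tPred, tTarget,
                      lambda = 1, nReg = length(anchorLabels),
                      eps = 1e-12) {
  probs <- as.matrix(probs)
  lcls <- -mean(log(pmax(probs[cbind(seq_len(nrow(probs)), classTargets)],
                         eps)))
  pos <- which(anchorLabels == 1)
  lreg <- 0
  if (length(pos)) {
    u <- as.matrix(tPred)[pos, , drop = FALSE] -
      as.matrix(tTarget)[pos, , drop = FALSE]
    lreg <- sum(smoothL1(u))
  }
  lcls + lambda * lreg / max(1, nReg)
}
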