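## Ensemble vote fusion of the three per-frame label tracks and the
## evaluation metrics: per-frame precision, per-action precision, and the
## row-normalized confusion matrix.

#' Fuse three per-frame label tracks by majority vote
#'
#' If at least two of the three networks vote the same label for a frame,
#' that label is assigned; otherwise the frame is labeled background
#' ("none of the above"). The rule is symmetric in the three inputs.
#'
#' @param trackCdc,trackRc3d,trackRhcn \linkS4class{FrameLabelTrack}s of
#'   equal length (character vectors are accepted).
#' @return the fused \linkS4class{FrameLabelTrack}.
#' @examples
#' fuseFrameVotes(c("walking", "walking"),
#'                c("walking", "reaching_forward"),
#'                c("none_of_the_above", "hand_manipulation"))
#' @export
fuseFrameVotes <- function(trackCdc, trackRc3d, trackRhcn) {
  lab <- function(x) if (is(x, "FrameLabelTrack")) x@labels else
    as.character(x)
  a <- lab(trackCdc); b <- lab(trackRc3d); c <- lab(trackRhcn)
  if (length(a) != length(b) || length(b) != length(c))
    stop("the three tracks must have equal length")
  fused <- ifelse(a == b | a == c, a,
                  ifelse(b == c, b, backgroundLabel()))
  FrameLabelTrack(fused)
}

#' Per-frame precision
#'
#' Fraction of frames whose predicted label equals the ground truth (micro
#' accuracy over all frames, background included). The macro per-class
#' variant and the background-excluded variant are available via
#' \code{\link{metricsReport}}.
#'
#' @param pred,gt \linkS4class{FrameLabelTrack}s (or label vectors) of
#'   equal length.
#' @return numeric in [0, 1].
#' @export
perFramePrecision <- function(pred, gt) {
  p <- if (is(pred, "FrameLabelTrack")) pred@labels else as.character(pred)
  g <- if (is(gt, "FrameLabelTrack")) gt@labels else as.character(gt)
  if (length(p) != length(g)) stop("tracks must have equal length")
  if (!length(p)) return(NaN)
  mean(p == g)
}

#' Per-action precision
#'
#' Fraction of predicted non-background segments that are matched
#' one-to-one (greedily by descending score, then IoU) to a same-label
#' ground-truth segment with temporal IoU at or above \code{iouThr}.
#'
#' @param pred,gt \linkS4class{ActionSegments}.
#' @param iouThr matching threshold (default 0.5).
#' @return numeric in [0, 1]; defined as 0 (with a warning attribute) when
#'   there are no predicted action segments.
#' @export
perActionPrecision <- function(pred, gt, iouThr = 0.5) {
  pDf <- segmentTable(pred)
  pDf <- pDf[pDf$label != backgroundLabel(), , drop = FALSE]
  gDf <- segmentTable(gt)
  gDf <- gDf[gDf$label != backgroundLabel(), , drop = FALSE]
  if (!nrow(pDf)) {
    out <- 0
    attr(out, "noPredictions") <- TRUE
    warning("no predicted action segments; per-action precision is 0")
    return(out)
  }
  pDf <- pDf[order(-pDf$score, pDf$start), , drop = FALSE]
  used <- logical(nrow(gDf))
  matched <- 0L
  for (i in seq_len(nrow(pDf))) {
    if (!nrow(gDf)) break
    iou <- temporalIoU(pDf$start[i], pDf$end[i], gDf$start, gDf$end)
    iou[used | gDf$label != pDf$label[i]] <- -1
    j <- which.max(iou)
    if (iou[j] >= iouThr) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched / nrow(pDf)
}

#' Per-frame confusion matrix
#'
#' Counts and the row-normalized matrix with ground truth on rows and
#' predictions on columns; rows of absent classes stay all-zero.
#'
#' @param pred,gt \linkS4class{FrameLabelTrack}s (or label vectors).
#' @return list with \code{counts} and \code{normalized}, both
#'   (K+1) x (K+1) matrices over \code{actionTaxonomy()}.
#' @export
confusionMatrix <- function(pred, gt) {
  p <- if (is(pred, "FrameLabelTrack")) pred@labels else as.character(pred)
  g <- if (is(gt, "FrameLabelTrack")) gt@labels else as.character(gt)
  if (length(p) != length(g)) stop("tracks must have equal length")
  lev <- actionTaxonomy()
  counts <- table(factor(g, levels = lev), factor(p, levels = lev))
  counts <- matrix(as.numeric(counts), length(lev), length(lev),
                   dimnames = list(truth = lev, prediction = lev))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, 1)
  list(counts = counts, normalized = normalized)
}

#' Full evaluation report
#'
#' @param predTrack,gtTrack per-frame tracks.
#' @param predSegments predicted \linkS4class{ActionSegments}; derived
#'   from \code{predTrack} when NULL.
#' @param gtSegments ground-truth segments; derived from \code{gtTrack}
#'   when NULL.
#' @param iouThr per-action matching threshold.
#' @return list of class \code{metricsReport}: per-frame precision (micro,
#'   micro excluding background frames, macro per class), per-action
#'   precision, confusion counts and normalized matrix.
#' @export
metricsReport <- function(predTrack, gtTrack, predSegments = NULL,
                          gtSegments = NULL, iouThr = 0.5) {
  if (is.null(predSegments)) predSegments <- segmentsFromTrack(predTrack)
  if (is.null(gtSegments)) gtSegments <- segmentsFromTrack(gtTrack)
  cm <- confusionMatrix(predTrack, gtTrack)
  p <- if (is(predTrack, "FrameLabelTrack")) predTrack@labels else predTrack
  g <- if (is(gtTrack, "FrameLabelTrack")) gtTrack@labels else gtTrack
  bg <- backgroundLabel()
  fg <- g != bg
  perClass <- diag(cm$normalized)
  present <- rowSums(cm$counts) > 0
  structure(list(
    perFramePrecision = perFramePrecision(p, g),
    perFramePrecisionNoBg = if (any(fg)) mean(p[fg] == g[fg]) else NaN,
    perFrameMacro = if (any(present)) mean(perClass[present]) else NaN,
    perActionPrecision = suppressWarnings(
      perActionPrecision(predSegments, gtSegments, iouThr)),
    confusion = cm$normalized, counts = cm$counts, iouThr = iouThr),
    class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat(sprintf("per-frame precision:  %.3f (excl. background %.3f, macro %.3f)\n",
              x$perFramePrecision, x$perFramePrecisionNoBg, x$perFrameMacro))
  cat(sprintf("per-action precision: %.3f (IoU >= %.2f)\n",
              x$perActionPrecision, x$iouThr))
  cat("confusion (rows = truth):\n")
  print(round(x$confusion, 3))
  invisible(x)
}
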