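## Shared proposal + classification machinery of the two segment detectors:
## a temporal proposal subnet over anchor segments (objectness + offsets at
## every feature-map position) and a classification/refinement subnet on
## RoI-pooled proposal features. Both losses follow the joint
## classification + smooth-L1 regression objective.

#' Temporal RoI max pooling
#'
#' Maps a variable-length interval of a temporal feature map to a fixed
#' number of features by splitting the interval into \code{outLen} equal
#' bins and max-pooling each bin (the temporal analogue of RoI pooling in
#' 2D detection). A bin narrower than one position falls back to its
#' leftmost position, so the output length is always \code{outLen}.
#'
#' @param featureMap C x T matrix (or length-T vector for one channel) of
#'   features at T temporal positions.
#' @param segment half-open interval \code{c(start, end)} in feature-map
#'   coordinates (0-based), non-empty, within \code{[0, T]}.
#' @param outLen number of output bins (>= 1).
#' @return C x outLen matrix of pooled features (a vector when C = 1).
#' @examples
#' roiPoolTemporal(c(1, 5, 3, 9), c(0, 4), 2)  # 5 9
#' @export
roiPoolTemporal <- function(featureMap, segment, outLen) {
  if (is.null(dim(featureMap))) featureMap <- matrix(featureMap, 1L)
  r <- roiPoolArgmax(featureMap, segment, outLen)
  if (nrow(r$pooled) == 1L) drop(r$pooled) else r$pooled
}

roiPoolArgmax <- function(featureMap, segment, outLen) {
  Tn <- ncol(featureMap)
  s <- segment[1L]; e <- segment[2L]
  if (e <= s) stop("RoI segment must be non-empty")
  if (s < 0 || e > Tn) stop("RoI segment outside the feature-map extent")
  w <- e - s
  pooled <- matrix(0, nrow(featureMap), outLen)
  argmax <- matrix(0L, nrow(featureMap), outLen)
  for (i in seq_len(outLen)) {
    b0 <- s + (i - 1L) * w / outLen
    b1 <- s + i * w / outLen
    p0 <- max(floor(s), floor(b0))
    p1 <- min(ceiling(e) - 1, ceiling(b1) - 1)
    if (p1 < p0) p1 <- p0
    idx <- (p0:p1) + 1L
    sub <- featureMap[, idx, drop = FALSE]
    am <- max.col(sub, ties.method = "first")
    pooled[, i] <- sub[cbind(seq_len(nrow(sub)), am)]
    argmax[, i] <- idx[am]
  }
  list(pooled = pooled, argmax = argmax)
}

## ---- detector core ---------------------------------------------------------

sdCoreBuild <- function(cin, nScales, nClasses, propWidth = 16L,
                        fcWidth = 32L, roiOutLen = 4L) {
  prop <- list(nnConv3(c(1L, 1L, 3L), cin, propWidth), nnRelu(),
               nnConv3(c(1L, 1L, 1L), propWidth, nScales * 4L))
  roi <- list(nnDense(cin * roiOutLen, fcWidth), nnRelu(),
              nnDense(fcWidth, fcWidth), nnRelu(),
              nnDense(fcWidth, nClasses * 3L))
  list(prop = prop, roi = roi, nScales = nScales, nClasses = nClasses,
       roiOutLen = roiOutLen, cin = cin)
}

## feature map Ft has dims (1, 1, T', B, C)
sdPropForward <- function(core, Ft, keepCache = FALSE) {
  netForward(core$prop, Ft, keepCache)
}

## anchor-major (position outer, scale inner) 4-column view of the
## proposal output for one batch element: (logit_bg, logit_fg, tx, tw)
sdAnchorView <- function(propOut, b, nScales) {
  Tp <- dim(propOut)[3L]
  m <- matrix(propOut[1L, 1L, , b, ], Tp, dim(propOut)[5L])
  out <- matrix(0, Tp * nScales, 4L)
  for (s in seq_len(nScales)) {
    rows <- (seq_len(Tp) - 1L) * nScales + s
    out[rows, ] <- m[, (s - 1L) * 4L + 1:4]
  }
  out
}

sdAnchorGradToPropOut <- function(dAnchor, Tp, nScales) {
  dm <- matrix(0, Tp, nScales * 4L)
  for (s in seq_len(nScales)) {
    rows <- (seq_len(Tp) - 1L) * nScales + s
    dm[, (s - 1L) * 4L + 1:4] <- dAnchor[rows, ]
  }
  dm
}

## deterministic RoI sampling around the ground truth for classifier training
sdSampleRois <- function(gtDf, T, nNeg = 4L) {
  rois <- list()
  for (g in seq_len(nrow(gtDf))) {
    s <- gtDf$start[g]; e <- gtDf$end[g]; w <- e - s
    cand <- rbind(c(s, e),
                  c(s - 0.1 * w, e + 0.1 * w),
                  c(s + 0.15 * w, e - 0.05 * w),
                  c(s - 0.15 * w, e - 0.1 * w))
    for (r in seq_len(nrow(cand))) {
      cs <- max(0, cand[r, 1L]); ce <- min(T, cand[r, 2L])
      if (ce - cs >= 1)
        rois[[length(rois) + 1L]] <- list(start = cs, end = ce,
                                          label = gtDf$label[g],
                                          gtStart = s, gtEnd = e)
    }
  }
  ## negatives: windows with low IoU against every ground truth
  tries <- 0L
  while (nNeg > 0L && tries < 50L) {
    tries <- tries + 1L
    w <- runif(1, 4, max(8, T / 3))
    s <- runif(1, 0, max(0.01, T - w))
    iou <- if (nrow(gtDf))
      max(temporalIoU(s, s + w, gtDf$start, gtDf$end)) else 0
    if (iou < 0.3) {
      rois[[length(rois) + 1L]] <- list(start = s, end = min(T, s + w),
                                        label = backgroundLabel(),
                                        gtStart = NA, gtEnd = NA)
      nNeg <- nNeg - 1L
    }
  }
  rois
}

## loss + gradients of both subnets for one batch of sessions.
## Ft: (1,1,T',B,C); gtList: per-session ActionSegments (frame units);
## Tframes: per-session unpadded length. Returns loss, grads and dFt.
sdLossGrads <- function(core, Ft, gtList, Tframes, stride, scales, cfg) {
  d <- dim(Ft)
  Tp <- d[3L]; B <- d[4L]; C <- d[5L]
  fp <- sdPropForward(core, Ft, keepCache = TRUE)
  propOut <- fp$y
  dPropOut <- array(0, dim = dim(propOut))
  dFt <- array(0, dim = d)
  nS <- core$nScales
  K1 <- core$nClasses
  taxonomy <- actionTaxonomy()
  totalLoss <- 0
  roiX <- NULL; roiTgt <- NULL; roiMeta <- list()
  anchors <- generateAnchors(Tp, scales, stride)
  for (b in seq_len(B)) {
    gtDf <- segmentTable(gtList[[b]])
    gtDf <- gtDf[gtDf$label != backgroundLabel(), , drop = FALSE]
    tgt <- assignAnchorTargets(anchors, gtList[[b]], cfg$posThr, cfg$negThr)
    av <- sdAnchorView(propOut, b, nS)
    lab <- tgt$label
    use <- which(!is.na(lab))
    wts <- numeric(length(lab))
    nPos <- sum(lab[use] == 1); nNegA <- sum(lab[use] == 0)
    wts[use[lab[use] == 1]] <- 1
    if (nNegA > 0)
      wts[use[lab[use] == 0]] <- if (nPos > 0) nPos / nNegA else 1
    tgtIdx <- ifelse(is.na(lab), 1L, lab + 1L)  # NA rows carry zero weight
    ce <- softmaxXent(av[, 1:2, drop = FALSE], tgtIdx, wts)
    dAnchor <- matrix(0, nrow(av), 4L)
    dAnchor[, 1:2] <- ce$grad
    loss <- ce$loss
    pos <- which(lab == 1)
    if (length(pos)) {
      ## normalize the regression term by the positive count so boundary
      ## offsets get a usable gradient at desk scale
      nReg <- length(pos)
      u <- av[pos, 3:4, drop = FALSE] -
        cbind(tgt$tx[pos], tgt$tw[pos])
      loss <- loss + cfg$lambda * sum(smoothL1(u)) / nReg
      dAnchor[pos, 3:4] <- cfg$lambda * smoothL1Grad(u) / nReg
    }
    dPropOut[1L, 1L, , b, ] <- dPropOut[1L, 1L, , b, ] +
      sdAnchorGradToPropOut(dAnchor, Tp, nS)
    totalLoss <- totalLoss + loss
    ## classifier RoIs: ground-truth-anchored samples plus the current
    ## top-scoring decoded proposals, labeled by their IoU against the
    ## ground truth, so the refinement subnet trains on the same proposal
    ## distribution it sees at detection time
    rois <- sdSampleRois(gtDf, Tframes[b])
    fgScore <- softmaxRows(av[, 1:2, drop = FALSE])[, 2L]
    topA <- order(-fgScore)[seq_len(min(4L, length(fgScore)))]
    decTop <- decodeOffsets(av[topA, 3L], av[topA, 4L],
                            anchors$center[topA], anchors$length[topA])
    for (q in seq_along(topA)) {
      ps <- max(0, decTop$center[q] - decTop$length[q] / 2)
      pe <- min(Tframes[b], decTop$center[q] + decTop$length[q] / 2)
      if (pe - ps < 1) next
      lab2 <- backgroundLabel(); gs <- NA; ge <- NA
      if (nrow(gtDf)) {
        iou <- temporalIoU(ps, pe, gtDf$start, gtDf$end)
        g <- which.max(iou)
        if (iou[g] >= 0.5) {
          lab2 <- gtDf$label[g]; gs <- gtDf$start[g]; ge <- gtDf$end[g]
        } else if (iou[g] >= 0.3) next  # ambiguous: skip
      }
      rois[[length(rois) + 1L]] <- list(start = ps, end = pe, label = lab2,
                                        gtStart = gs, gtEnd = ge)
    }
    fm <- t(matrix(Ft[1L, 1L, , b, ], Tp, C))   # C x T'
    for (r in rois) {
      seg <- c(r$start, r$end) / stride
      seg[2L] <- min(seg[2L], Tp)
      if (seg[2L] - seg[1L] <= 0) next
      rp <- roiPoolArgmax(fm, seg, core$roiOutLen)
      roiX <- rbind(roiX, as.vector(rp$pooled))
      roiMeta[[length(roiMeta) + 1L]] <-
        list(b = b, argmax = rp$argmax, label = match(r$label, taxonomy),
             roi = c(r$start, r$end), gt = c(r$gtStart, r$gtEnd))
    }
  }
  nR <- length(roiMeta)
  if (nR > 0L) {
    fr <- netForward(core$roi, roiX, keepCache = TRUE)
    out <- fr$y                       # nR x (K1 * 3)
    labels <- vapply(roiMeta, `[[`, 0L, "label")
    ce <- softmaxXent(out[, seq_len(K1), drop = FALSE], labels)
    dOut <- matrix(0, nR, K1 * 3L)
    dOut[, seq_len(K1)] <- ce$grad
    loss <- ce$loss
    isPos <- vapply(roiMeta, function(m)
      !is.na(m$gt[1L]) && m$label != match(backgroundLabel(), taxonomy),
      logical(1))
    nRegR <- max(1L, sum(isPos))
    for (i in which(isPos)) {
      m <- roiMeta[[i]]
      xa <- mean(m$roi); wa <- m$roi[2L] - m$roi[1L]
      enc <- encodeOffsets(mean(m$gt), m$gt[2L] - m$gt[1L], xa, wa)
      cols <- K1 + (m$label - 1L) * 2L + 1:2
      u <- out[i, cols] - c(enc$tx, enc$tw)
      loss <- loss + cfg$lambda * sum(smoothL1(u)) / nRegR
      dOut[i, cols] <- cfg$lambda * smoothL1Grad(u) / nRegR
    }
    totalLoss <- totalLoss + loss
    br <- netBackward(core$roi, fr$caches, dOut)
    ## scatter RoI feature gradients back into the feature map
    for (i in seq_len(nR)) {
      m <- roiMeta[[i]]
      dPool <- matrix(br$dx[i, ], C, core$roiOutLen)
      for (bin in seq_len(core$roiOutLen)) {
        tpos <- m$argmax[, bin]
        for (c0 in seq_len(C))
          dFt[1L, 1L, tpos[c0], m$b, c0] <-
            dFt[1L, 1L, tpos[c0], m$b, c0] + dPool[c0, bin]
      }
    }
    roiGrads <- br$grads
  } else roiGrads <- NULL
  bp <- netBackward(core$prop, fp$caches, dPropOut)
  dFt <- dFt + bp$dx
  list(loss = totalLoss / B, dFt = dFt, propGrads = bp$grads,
       roiGrads = roiGrads)
}

## detection for one batch element given its feature map
sdDetect <- function(core, Ft, b, Tframes, stride, scales, cfg,
                     restrictLabels = NULL) {
  d <- dim(Ft)
  Tp <- d[3L]; C <- d[5L]
  taxonomy <- actionTaxonomy()
  K1 <- core$nClasses
  propOut <- sdPropForward(core, Ft)$y
  av <- sdAnchorView(propOut, b, core$nScales)
  anchors <- generateAnchors(Tp, scales, stride)
  fg <- softmaxRows(av[, 1:2, drop = FALSE])[, 2L]
  dec <- decodeOffsets(av[, 3L], av[, 4L], anchors$center, anchors$length)
  start <- pmax(0, dec$center - dec$length / 2)
  end <- pmin(Tframes, dec$center + dec$length / 2)
  ok <- which(end - start >= 1 & fg >= cfg$propMinScore)
  if (!length(ok)) {
    return(list(segments = ActionSegments(),
                track = FrameLabelTrack(rep(backgroundLabel(), Tframes))))
  }
  props <- ActionSegments(start[ok], end[ok],
                          rep(backgroundLabel(), length(ok)), fg[ok])
  props <- nmsSegments(props, cfg$nmsProposal)
  pdf <- utils::head(segmentTable(props), cfg$maxProposals)
  fm <- t(matrix(Ft[1L, 1L, , b, ], Tp, C))
  dets <- NULL
  for (i in seq_len(nrow(pdf))) {
    seg <- c(pdf$start[i], pdf$end[i]) / stride
    seg[2L] <- min(seg[2L], Tp)
    if (seg[2L] - seg[1L] <= 0) next
    rp <- roiPoolArgmax(fm, seg, core$roiOutLen)
    out <- netForward(core$roi, matrix(as.vector(rp$pooled), 1L))$y
    probs <- softmaxRows(out[, seq_len(K1), drop = FALSE])
    k <- which.max(probs)
    if (taxonomy[k] == backgroundLabel()) next
    if (probs[k] < cfg$scoreThr) next
    cols <- K1 + (k - 1L) * 2L + 1:2
    xa <- (pdf$start[i] + pdf$end[i]) / 2
    wa <- pdf$end[i] - pdf$start[i]
    ref <- decodeOffsets(out[1L, cols[1L]], out[1L, cols[2L]], xa, wa)
    s2 <- max(0, ref$center - ref$length / 2)
    e2 <- min(Tframes, ref$center + ref$length / 2)
    if (e2 - s2 < 1) next
    dets <- rbind(dets, data.frame(start = s2, end = e2,
                                   label = taxonomy[k],
                                   score = probs[k]))
  }
  if (is.null(dets) || !nrow(dets)) {
    return(list(segments = ActionSegments(),
                track = FrameLabelTrack(rep(backgroundLabel(), Tframes))))
  }
  if (!is.null(restrictLabels))
    dets <- dets[dets$label %in% restrictLabels, , drop = FALSE]
  if (!nrow(dets)) {
    return(list(segments = ActionSegments(),
                track = FrameLabelTrack(rep(backgroundLabel(), Tframes))))
  }
  final <- NULL
  for (cl in unique(dets$label)) {
    sub <- dets[dets$label == cl, , drop = FALSE]
    kept <- nmsSegments(ActionSegments(sub$start, sub$end, sub$label,
                                       sub$score), cfg$nmsFinal)
    final <- rbind(final, segmentTable(kept))
  }
  segs <- ActionSegments(round(final$start), round(pmax(final$start + 1,
                                                        final$end)),
                         final$label, final$score)
  segs@segments <- segs@segments[segs@segments$end > segs@segments$start, ,
                                 drop = FALSE]
  list(segments = segs, track = trackFromSegments(segs, Tframes))
}
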