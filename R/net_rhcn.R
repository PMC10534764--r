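## Region hierarchical co-occurrence network: skeleton + motion streams
## through point-level layers (kernel 1 along the joint axis), a transform
## stage that swaps the joint and coordinate axes so subsequent layers learn
## global joint co-occurrences, stream concatenation, and the shared
## temporal proposal / classification subnets.

#' Skeletal motion: temporal joint differences
#'
#' The motion representation M_t = S_{t+1} - S_t for every joint and axis;
#' the final frame is zero-padded so the motion stream has the same shape
#' as the skeleton stream.
#'
#' @param S a \linkS4class{SkeletonSequence} or T x N x 3 array, T >= 2.
#' @return array of the same shape as the input joints.
#' @examples
#' S <- array(c(0, 1, 3), dim = c(3, 1, 1))
#' skeletonMotion(array(S, dim = c(3, 19, 3)))[, 1, 1]  # 1 2 0
#' @export
skeletonMotion <- function(S) {
  if (is(S, "SkeletonSequence")) S <- S@joints
  T <- dim(S)[1L]
  if (T < 2L) stop("at least 2 frames are needed for the motion stream")
  M <- array(0, dim = dim(S))
  M[seq_len(T - 1L), , ] <- S[2:T, , , drop = FALSE] -
    S[seq_len(T - 1L), , , drop = FALSE]
  M
}

#' Configuration of the skeleton segment detector
#'
#' @param nJoints number of joints (19).
#' @param scales anchor lengths in frames (default c(50, 100, 200, 400)).
#' @param stride temporal stride of the feature map (4).
#' @param pointWidth,coocWidth,mergeWidth channel widths of the point-level,
#'   co-occurrence and merged stages.
#' @param fcWidth width of the fully connected classification stages.
#' @param roiOutLen pooled temporal length per proposal.
#' @param nClasses K + 1.
#' @param rootCenter subtract the mid-hip joint per frame before the
#'   network (default TRUE).
#' @param restrictLabels labels kept at detection time; skeletal data are
#'   noise-sensitive, so only walking detections are considered by default.
#' @param posThr,negThr,nmsProposal,nmsFinal,scoreThr,propMinScore,
#'   maxProposals,lambda as in \code{\link{rc3dConfig}}.
#' @return list of class \code{rhcnConfig}.
#' @export
rhcnConfig <- function(nJoints = 19L, scales = c(50, 100, 200, 400),
                       stride = 4L, pointWidth = 8L, coocWidth = 12L,
                       mergeWidth = 16L, fcWidth = 32L, roiOutLen = 4L,
                       nClasses = 6L, rootCenter = TRUE,
                       restrictLabels = "walking", posThr = 0.7,
                       negThr = 0.3, nmsProposal = 0.7, nmsFinal = 0.4,
                       scoreThr = 0.05, propMinScore = 0.05,
                       maxProposals = 8L, lambda = 1) {
  structure(list(nJoints = as.integer(nJoints), scales = scales,
                 stride = as.integer(stride), pointWidth = pointWidth,
                 coocWidth = coocWidth, mergeWidth = mergeWidth,
                 fcWidth = fcWidth, roiOutLen = as.integer(roiOutLen),
                 nClasses = as.integer(nClasses), rootCenter = rootCenter,
                 restrictLabels = restrictLabels, posThr = posThr,
                 negThr = negThr, nmsProposal = nmsProposal,
                 nmsFinal = nmsFinal, scoreThr = scoreThr,
                 propMinScore = propMinScore, maxProposals = maxProposals,
                 lambda = lambda), class = "rhcnConfig")
}

rhcnStreamLayers <- function(cfg) {
  list(nnConv3(c(1L, 1L, 3L), 3L, cfg$pointWidth), nnRelu(),   # point level 1
       nnConv3(c(1L, 1L, 3L), cfg$pointWidth, cfg$pointWidth), nnRelu(),
       nnPermNC(),                                             # joints <-> channels
       nnConv3(c(3L, 1L, 3L), cfg$nJoints, cfg$coocWidth), nnRelu(),
       nnPool(c(1L, 1L, 2L)),
       nnConv3(c(3L, 1L, 3L), cfg$coocWidth, cfg$coocWidth), nnRelu(),
       nnPool(c(1L, 1L, 2L)))
}

#' Build the skeleton segment detector
#'
#' @param config an \code{\link{rhcnConfig}}.
#' @param seed integer seed.
#' @return model list of class \code{rhcnModel}.
#' @export
buildRhcn <- function(config = rhcnConfig(), seed = 0) {
  stopifnot(inherits(config, "rhcnConfig"))
  withSeed(seed, {
    streamS <- rhcnStreamLayers(config)
    streamM <- rhcnStreamLayers(config)
    merge <- list(nnFlatDense(config$pointWidth, 1L, 2L * config$coocWidth,
                              config$mergeWidth),
                  nnRelu(),
                  nnConv3(c(1L, 1L, 3L), config$mergeWidth,
                          config$mergeWidth), nnRelu())
    core <- sdCoreBuild(config$mergeWidth, length(config$scales),
                        config$nClasses, propWidth = 16L,
                        fcWidth = config$fcWidth,
                        roiOutLen = config$roiOutLen)
  })
  structure(list(config = config, streamS = streamS, streamM = streamM,
                 merge = merge, core = core, iterations = 0L,
                 history = numeric(0)),
            class = "rhcnModel")
}

## stack skeleton sequences into the two input streams, padded to a stride
## multiple: arrays (N, 1, T, B, 3)
rhcnBatchInput <- function(skels, cfg) {
  Ts <- vapply(skels, nFrames, 0L)
  Tpad <- max(ceiling(Ts / cfg$stride)) * cfg$stride
  B <- length(skels)
  xS <- array(0, dim = c(cfg$nJoints, 1L, Tpad, B, 3L))
  xM <- xS
  for (k in seq_len(B)) {
    S <- skels[[k]]@joints
    if (anyNA(S)) S <- imputeJoints(skels[[k]])@joints
    if (cfg$rootCenter) {
      root <- S[, match("mid_hip", jointTemplate()), , drop = FALSE]
      S <- S - root[, rep(1L, 19L), , drop = FALSE]
    }
    M <- skeletonMotion(S)
    idx <- c(seq_len(Ts[k]), rep(Ts[k], Tpad - Ts[k]))
    xS[, 1L, , k, ] <- aperm(S[idx, , , drop = FALSE], c(2L, 1L, 3L))
    xM[, 1L, , k, ] <- aperm(M[idx, , , drop = FALSE], c(2L, 1L, 3L))
  }
  list(xS = xS, xM = xM, Ts = Ts, Tpad = Tpad)
}

rhcnEncode <- function(model, bt, keepCache = FALSE) {
  fS <- netForward(model$streamS, bt$xS, keepCache)
  fM <- netForward(model$streamM, bt$xM, keepCache)
  cS <- dim(fS$y)[5L]
  x <- array(0, dim = c(dim(fS$y)[1:4], 2L * cS))
  x[, , , , seq_len(cS)] <- fS$y
  x[, , , , cS + seq_len(cS)] <- fM$y
  fMg <- netForward(model$merge, x, keepCache)
  list(Ft = fMg$y, fS = fS, fM = fM, fMg = fMg, cS = cS)
}

#' Train the skeleton segment detector
#'
#' Same optimization scheme and hyper profiles as the depth segment
#' detector; supervision is segment-level through the proposal and
#' classification subnets.
#'
#' @param model an \code{rhcnModel}.
#' @param sessions list of \linkS4class{HomeSession} (the primary skeleton
#'   stream of each is used).
#' @param hyper e.g. \code{hyperProfile("desk")$rhcn}.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return the trained model.
#' @export
trainRhcn <- function(model, sessions, hyper = hyperProfile("desk")$rhcn,
                      seed = 0, verbose = FALSE) {
  cfg <- model$config
  state <- sgdState()
  mth <- if (is.null(hyper$method)) "sgd" else hyper$method
  n <- length(sessions)
  skels <- lapply(sessions, function(s) sessionSkeletons(s)[[1L]])
  gts <- lapply(sessions, function(s) segmentsFromTrack(sessionTrack(s)))
  withSeed(seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = hyper$batch)) {
        bi <- ord[b0:min(b0 + hyper$batch - 1L, n)]
        bt <- rhcnBatchInput(skels[bi], cfg)
        enc <- rhcnEncode(model, bt, keepCache = TRUE)
        lg <- sdLossGrads(model$core, enc$Ft, gts[bi], bt$Ts, cfg$stride,
                          cfg$scales, cfg)
        bMg <- netBackward(model$merge, enc$fMg$caches, lg$dFt)
        cS <- enc$cS
        dS <- bMg$dx[, , , , seq_len(cS), drop = FALSE]
        dM <- bMg$dx[, , , , cS + seq_len(cS), drop = FALSE]
        bS <- netBackward(model$streamS, enc$fS$caches, dS)
        bM <- netBackward(model$streamM, enc$fM$caches, dM)
        lr <- cdcLrAt(hyper, model$iterations)
        model$streamS <- sgdUpdate(model$streamS, bS$grads, state, lr,
                                   hyper$momentum, hyper$weightDecay, "s", mth)
        model$streamM <- sgdUpdate(model$streamM, bM$grads, state, lr,
                                   hyper$momentum, hyper$weightDecay, "m", mth)
        model$merge <- sgdUpdate(model$merge, bMg$grads, state, lr,
                                 hyper$momentum, hyper$weightDecay, "g", mth)
        model$core$prop <- sgdUpdate(model$core$prop, lg$propGrads, state,
                                     lr, hyper$momentum, hyper$weightDecay,
                                     "p", mth)
        if (!is.null(lg$roiGrads))
          model$core$roi <- sgdUpdate(model$core$roi, lg$roiGrads, state,
                                      lr, hyper$momentum, hyper$weightDecay,
                                      "r", mth)
        state$step <- state$step + 1L
        model$iterations <- model$iterations + 1L
        epLoss <- epLoss + lg$loss; nb <- nb + 1L
      }
      model$history <- c(model$history, epLoss / nb)
      if (verbose)
        message(sprintf("rhcn epoch %d: loss %.4f", ep, epLoss / nb))
    }
  })
  model
}

#' Detect action segments in a skeleton stream
#'
#' Identical detection pipeline to the depth detector; detections whose
#' label is outside \code{restrictLabels} are discarded and their frames
#' revert to background (the default keeps walking only, because skeletal
#' joint data are more noise-sensitive).
#'
#' @param model a trained \code{rhcnModel}.
#' @param skeleton a \linkS4class{SkeletonSequence}.
#' @param restrictLabels labels to keep; NULL keeps all. Defaults to the
#'   model configuration.
#' @return list with \code{segments} and \code{track}.
#' @export
detectRhcn <- function(model, skeleton, restrictLabels = NULL) {
  cfg <- model$config
  if (is.null(restrictLabels)) restrictLabels <- cfg$restrictLabels
  if (length(restrictLabels) == 1L && identical(restrictLabels, "all"))
    restrictLabels <- NULL
  T <- nFrames(skeleton)
  if (T < 2L)
    return(list(segments = ActionSegments(),
                track = FrameLabelTrack(rep(backgroundLabel(), T))))
  bt <- rhcnBatchInput(list(skeleton), cfg)
  enc <- rhcnEncode(model, bt)
  sdDetect(model$core, enc$Ft, 1L, bt$Ts[1L], cfg$stride, cfg$scales, cfg,
           restrictLabels = restrictLabels)
}
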