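## Anchor-based segment detector on depth windows: a shared 3D-conv feature
## extractor (temporal stride 8), a temporal proposal subnet over ten anchor
## scales, temporal RoI pooling, and a classification + boundary-refinement
## subnet.

#' Configuration of the depth segment detector
#'
#' @param inputSize spatial input size, multiples of 28 (the backbone is
#'   the same five-stage 3D-conv ladder as the per-frame scorer, ending in
#'   a spatial collapse to a temporal-only feature map at stride 8).
#' @param scales anchor lengths in frames; the default is the ten scales
#'   2, 4, 5, 6, 8, 9, 10, 12, 14, 16.
#' @param roiOutLen pooled temporal length of each proposal (default 4).
#' @param widths 5 backbone channel widths.
#' @param propWidth,fcWidth widths of the proposal conv and the two fully
#'   connected stages.
#' @param nClasses K + 1 (default 6).
#' @param posThr,negThr anchor assignment IoU thresholds (0.7 / 0.3).
#' @param nmsProposal,nmsFinal NMS IoU thresholds at the proposal and
#'   detection stages (0.7 / 0.4).
#' @param scoreThr minimum detection score (0.05).
#' @param propMinScore minimum proposal objectness kept (0.05).
#' @param maxProposals proposals forwarded to classification.
#' @param lambda regression trade-off weight in the joint loss.
#' @param depthRef,depthSpan input normalization as in \code{\link{cdcConfig}}.
#' @return list of class \code{rc3dConfig}.
#' @export
rc3dConfig <- function(inputSize = c(28L, 28L),
                       scales = c(2, 4, 5, 6, 8, 9, 10, 12, 14, 16),
                       roiOutLen = 4L, widths = c(4L, 8L, 16L, 24L, 32L),
                       propWidth = 24L, fcWidth = 48L, nClasses = 6L,
                       posThr = 0.7, negThr = 0.3, nmsProposal = 0.7,
                       nmsFinal = 0.4, scoreThr = 0.05,
                       propMinScore = 0.05, maxProposals = 8L,
                       lambda = 1, depthRef = DEPTH_REF_MM,
                       depthSpan = DEPTH_SPAN_MM) {
  if (!length(scales) || is.unsorted(scales))
    stop("anchor scales must be non-empty and ascending")
  if (roiOutLen < 1L) stop("roiOutLen must be >= 1")
  if (any(inputSize %% 28L != 0L))
    stop("spatial input size must be a multiple of 28")
  structure(list(inputSize = as.integer(inputSize), scales = scales,
                 stride = 8L, roiOutLen = as.integer(roiOutLen),
                 widths = as.integer(widths), propWidth = propWidth,
                 fcWidth = fcWidth, nClasses = as.integer(nClasses),
                 posThr = posThr, negThr = negThr,
                 nmsProposal = nmsProposal, nmsFinal = nmsFinal,
                 scoreThr = scoreThr, propMinScore = propMinScore,
                 maxProposals = maxProposals, lambda = lambda,
                 depthRef = depthRef, depthSpan = depthSpan),
            class = "rc3dConfig")
}

#' Build the depth segment detector
#'
#' @param config an \code{\link{rc3dConfig}}.
#' @param seed integer seed for weight initialization.
#' @return model list of class \code{rc3dModel}.
#' @export
buildRc3d <- function(config = rc3dConfig(), seed = 0) {
  stopifnot(inherits(config, "rc3dConfig"))
  w <- config$widths
  edge <- config$inputSize
  for (i in 1:5) edge <- ceiling(edge / 2L)
  withSeed(seed, {
    backbone <- cdcBackboneLayers(
      cdcConfig(config$inputSize, 16L, c(w, 1L, 1L), config$nClasses))
    if (any(edge > 1L))  # collapse leftover space to a temporal-only map
      backbone <- c(backbone, list(nnPool(c(edge[1L], edge[2L], 1L))))
    core <- sdCoreBuild(w[5L], length(config$scales), config$nClasses,
                        config$propWidth, config$fcWidth, config$roiOutLen)
  })
  structure(list(config = config, backbone = backbone, core = core,
                 iterations = 0L, history = numeric(0)),
            class = "rc3dModel")
}

## pad session depth to a multiple of the temporal stride and stack a batch
rc3dBatchInput <- function(sessions, cfg) {
  Ts <- vapply(sessions, nFrames, 0L)
  Tpad <- max(ceiling(Ts / cfg$stride)) * cfg$stride
  B <- length(sessions)
  x <- array(0, dim = c(cfg$inputSize, Tpad, B, 1L))
  for (k in seq_len(B)) {
    fr <- depthFrames(sessionDepth(sessions[[k]]))
    idx <- c(seq_len(Ts[k]), rep(Ts[k], Tpad - Ts[k]))
    x[, , , k, 1L] <- normalizeDepth(fr[, , idx], cfg)
  }
  list(x = x, Ts = Ts, Tpad = Tpad)
}

#' Train the depth segment detector
#'
#' Joint optimization of the proposal and classification subnets with the
#' combined softmax + smooth-L1 objective, by SGD with momentum. With the
#' \code{"paper"} hyper profile the published settings are used verbatim
#' (learning rate 1e-14: a frozen-feature regime); the \code{"desk"}
#' profile is the usable small-scale default.
#'
#' @param model an \code{rc3dModel}.
#' @param sessions list of \linkS4class{HomeSession} with ground truth.
#' @param hyper e.g. \code{hyperProfile("desk")$rc3d}.
#' @param seed integer seed.
#' @param verbose print per-epoch loss.
#' @return the trained model.
#' @export
trainRc3d <- function(model, sessions, hyper = hyperProfile("desk")$rc3d,
                      seed = 0, verbose = FALSE) {
  cfg <- model$config
  state <- sgdState()
  mth <- if (is.null(hyper$method)) "sgd" else hyper$method
  n <- length(sessions)
  gts <- lapply(sessions, function(s) segmentsFromTrack(sessionTrack(s)))
  withSeed(seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(n)
      epLoss <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = hyper$batch)) {
        bi <- ord[b0:min(b0 + hyper$batch - 1L, n)]
        bt <- rc3dBatchInput(sessions[bi], cfg)
        fb <- netForward(model$backbone, bt$x, keepCache = TRUE)
        lg <- sdLossGrads(model$core, fb$y, gts[bi], bt$Ts, cfg$stride,
                          cfg$scales, cfg)
        bb <- netBackward(model$backbone, fb$caches, lg$dFt)
        lr <- cdcLrAt(hyper, model$iterations)
        model$backbone <- sgdUpdate(model$backbone, bb$grads, state, lr,
                                    hyper$momentum, hyper$weightDecay, "b", mth)
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
        message(sprintf("rc3d epoch %d: loss %.4f", ep, epLoss / nb))
    }
  })
  model
}

#' Detect action segments in a depth sequence
#'
#' Runs the proposal subnet over the temporal feature map, applies greedy
#' NMS, pools each surviving proposal to a fixed-length feature, classifies
#' and refines its boundaries, applies per-class NMS, and paints the
#' resulting segments into a per-frame track (higher scores win overlaps;
#' background elsewhere). Segments are clipped to [0, T). Deterministic
#' given the model and input.
#'
#' @param model a trained \code{rc3dModel}.
#' @param depth a \linkS4class{DepthSequence}.
#' @return list with \code{segments} (\linkS4class{ActionSegments}) and
#'   \code{track} (\linkS4class{FrameLabelTrack}).
#' @export
detectRc3d <- function(model, depth) {
  cfg <- model$config
  session <- HomeSession(depth,
                         list(SkeletonSequence(
                           array(NA_real_, dim = c(nFrames(depth), 19L, 3L)))),
                         FrameLabelTrack(rep(backgroundLabel(),
                                             nFrames(depth))))
  bt <- rc3dBatchInput(list(session), cfg)
  Ft <- netForward(model$backbone, bt$x)$y
  sdDetect(model$core, Ft, 1L, bt$Ts[1L], cfg$stride, cfg$scales, cfg)
}
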