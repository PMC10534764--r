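## Per-frame action scorer: a 3D-conv backbone that downsamples space
## (112 -> 4 for the default geometry, i.e. by a factor 28) and time by 8,
## followed by convolutional-de-convolutional stages that collapse space to
## 1 x 1 and upsample time L/8 -> L/4 -> L/2 -> L, ending in a per-frame
## softmax over the K + 1 classes.

## foreground-contrast input normalization: the nominal background plane
## maps to 0 and everything depthSpan millimeters in front of it to 1, so
## the informative person-surface range uses the full activation scale
DEPTH_REF_MM <- 4000
DEPTH_SPAN_MM <- 2000

normalizeDepth <- function(frames, cfg) {
  pmin(1, pmax(0, (cfg$depthRef - frames) / cfg$depthSpan))
}

#' Configuration of the per-frame CDC scorer
#'
#' The spatial path follows the 112 -> 4 pattern (five conv + pool stages),
#' so the input edge must be a multiple of 28; the temporal path downsamples
#' by exactly 8 in the backbone and upsamples back to L in three
#' de-convolutional stages, so L must be divisible by 8. Channel widths are
#' scalable so that desk-scale tests can train a tiny model while the
#' default profile preserves the published geometry.
#'
#' @param inputSize spatial input size, c(H, W), multiples of 28.
#' @param L window length in frames, divisible by 8.
#' @param widths 7 channel widths: the five backbone stages and the two
#'   intermediate de-convolutional stages.
#' @param nClasses number of output classes (K + 1, default 6).
#' @param depthRef,depthSpan input normalization: pixels map to
#'   clamp((depthRef - depth) / depthSpan, 0, 1), so the nominal background
#'   plane is 0 and surfaces depthSpan mm in front of it are 1.
#' @return list of class \code{cdcConfig}.
#' @export
cdcConfig <- function(inputSize = c(112L, 112L), L = 16L,
                      widths = c(8L, 12L, 16L, 16L, 16L, 24L, 24L),
                      nClasses = 6L, depthRef = DEPTH_REF_MM,
                      depthSpan = DEPTH_SPAN_MM) {
  if (L %% 8L != 0L) stop("window length L must be divisible by 8")
  if (any(inputSize %% 28L != 0L))
    stop("spatial input size must be a multiple of 28 (112 -> 4 pattern)")
  if (length(widths) != 7L) stop("widths must have 7 entries")
  structure(list(inputSize = as.integer(inputSize), L = as.integer(L),
                 widths = as.integer(widths), nClasses = as.integer(nClasses),
                 depthRef = depthRef, depthSpan = depthSpan),
            class = "cdcConfig")
}

#' @rdname cdcConfig
#' @export
cdcDeskConfig <- function(inputSize = c(28L, 28L), L = 16L,
                          widths = c(4L, 8L, 8L, 8L, 8L, 16L, 16L),
                          nClasses = 6L) {
  cdcConfig(inputSize, L, widths, nClasses)
}

cdcBackboneLayers <- function(cfg) {
  w <- cfg$widths
  list(nnConv3(c(3L, 3L, 3L), 1L, w[1L]), nnRelu(), nnPool(c(2L, 2L, 1L)),
       nnConv3(c(3L, 3L, 3L), w[1L], w[2L]), nnRelu(), nnPool(c(2L, 2L, 2L)),
       nnConv3(c(3L, 3L, 3L), w[2L], w[3L]), nnRelu(), nnPool(c(2L, 2L, 2L)),
       nnConv3(c(3L, 3L, 3L), w[3L], w[4L]), nnRelu(), nnPool(c(2L, 2L, 2L)),
       nnConv3(c(3L, 3L, 3L), w[4L], w[5L]), nnRelu(), nnPool(c(2L, 2L, 1L)))
}

#' Build the per-frame CDC scorer
#'
#' @param config a \code{\link{cdcConfig}}.
#' @param seed integer seed for weight initialization.
#' @return model list of class \code{cdcModel} with \code{backbone} and
#'   \code{head} layer stacks.
#' @examples
#' m <- buildCdc(cdcDeskConfig())
#' out <- cdcForward(m, array(0, dim = c(28, 28, 16, 1, 1)))
#' dim(out$scores)   # (1, 1, 16, 1, 6): per-frame class scores
#' @export
buildCdc <- function(config = cdcConfig(), seed = 0) {
  stopifnot(inherits(config, "cdcConfig"))
  ## spatial edge after the five halvings (ceil): 112 -> 4, 28 -> 1
  edge <- config$inputSize
  for (i in 1:5) edge <- ceiling(edge / 2L)
  w <- config$widths
  withSeed(seed, {
    backbone <- cdcBackboneLayers(config)
    head <- list(
      nnFlatDense(edge[1L], edge[2L], w[5L], w[6L]),          # space -> 1x1
      nnUpT(), nnConv3(c(1L, 1L, 3L), w[6L], w[6L]), nnRelu(), # L/8 -> L/4
      nnUpT(), nnConv3(c(1L, 1L, 3L), w[6L], w[7L]), nnRelu(), # L/4 -> L/2
      nnUpT(), nnConv3(c(1L, 1L, 3L), w[7L], config$nClasses)) # L/2 -> L
  })
  structure(list(config = config, backbone = backbone, head = head,
                 iterations = 0L, history = numeric(0)),
            class = "cdcModel")
}

#' Forward pass of the CDC scorer
#'
#' @param model a \code{cdcModel}.
#' @param x input array, dims (H, W, L, B, 1), already normalized to [0, 1].
#' @param keepCache retain layer caches for backpropagation.
#' @return list with \code{scores} (logits, dims (1, 1, L, B, K + 1)),
#'   \code{backboneDim} (dims of the C3D-stage output), and caches.
#' @export
cdcForward <- function(model, x, keepCache = FALSE) {
  fb <- netForward(model$backbone, x, keepCache)
  fh <- netForward(model$head, fb$y, keepCache)
  list(scores = fh$y, backboneDim = dim(fb$y), backCaches = fb$caches,
       headCaches = fh$caches)
}

#' Split a depth sequence into fixed-length windows
#'
#' Applies the non-overlapping L-frame sliding window used to feed the
#' scorer; the last window is padded by repeating the final frame and the
#' padding mask is returned.
#'
#' @param depth a \linkS4class{DepthSequence}.
#' @param L window length (default 16).
#' @return list of windows, each a list with \code{frames} (H x W x L
#'   array), \code{valid} (logical length-L mask, FALSE on padding) and
#'   \code{start} (0-based frame offset).
#' @examples
#' d <- DepthSequence(array(0L, dim = c(4, 4, 20)))
#' length(windowVideo(d, 16))              # 2 windows
#' sum(!windowVideo(d, 16)[[2]]$valid)     # 12 padded frames
#' @export
windowVideo <- function(depth, L = 16L) {
  fr <- depthFrames(depth)
  T <- dim(fr)[3L]
  nWin <- ceiling(T / L)
  lapply(seq_len(nWin), function(i) {
    idx <- ((i - 1L) * L + 1L):min(i * L, T)
    valid <- rep(TRUE, length(idx))
    if (length(idx) < L) {
      pad <- L - length(idx)
      idx <- c(idx, rep(idx[length(idx)], pad))
      valid <- c(valid, rep(FALSE, pad))
    }
    list(frames = fr[, , idx, drop = FALSE], valid = valid,
         start = (i - 1L) * L)
  })
}

cdcLrAt <- function(hyper, iteration) {
  hyper$lr * hyper$lrDecay^(floor(iteration / hyper$lrStep))
}

#' Train the CDC scorer on labeled sessions
#'
#' Stochastic gradient descent with momentum on the per-frame softmax
#' cross-entropy; padded frames carry zero loss weight. The learning rate
#' follows a step schedule (decayed by \code{lrDecay} every \code{lrStep}
#' iterations). Deterministic under a fixed seed.
#'
#' @param model a \code{cdcModel}.
#' @param sessions list of \linkS4class{HomeSession} with ground-truth
#'   tracks.
#' @param hyper hyperparameter list, e.g. \code{hyperProfile("desk")$cdc}.
#' @param seed integer seed controlling shuffling.
#' @param verbose print per-epoch mean loss.
#' @return the trained \code{cdcModel} (loss history in \code{$history}).
#' @export
trainCdc <- function(model, sessions, hyper = hyperProfile("desk")$cdc,
                     seed = 0, verbose = FALSE) {
  cfg <- model$config
  taxonomy <- actionTaxonomy()
  wins <- list()
  for (s in sessions) {
    labIdx <- match(frameLabels(s), taxonomy)
    for (wv in windowVideo(sessionDepth(s), cfg$L)) {
      idx <- wv$start + seq_len(cfg$L)
      idx[!wv$valid] <- wv$start + sum(wv$valid)  # repeat last valid label
      wins[[length(wins) + 1L]] <-
        list(frames = wv$frames, labels = labIdx[idx], valid = wv$valid)
    }
  }
  state <- sgdState()
  mth <- if (is.null(hyper$method)) "sgd" else hyper$method
  nW <- length(wins)
  withSeed(seed, {
    for (ep in seq_len(hyper$epochs)) {
      ord <- sample.int(nW)
      epLoss <- 0; nb <- 0L
      for (b0 in seq(1L, nW, by = hyper$batch)) {
        bi <- ord[b0:min(b0 + hyper$batch - 1L, nW)]
        B <- length(bi)
        x <- array(0, dim = c(cfg$inputSize, cfg$L, B, 1L))
        tgt <- integer(cfg$L * B)
        wt <- numeric(cfg$L * B)
        for (k in seq_len(B)) {
          x[, , , k, 1L] <- normalizeDepth(wins[[bi[k]]]$frames, cfg)
          rows <- (k - 1L) * cfg$L + seq_len(cfg$L)
          tgt[rows] <- wins[[bi[k]]]$labels
          wt[rows] <- as.numeric(wins[[bi[k]]]$valid)
        }
        fw <- cdcForward(model, x, keepCache = TRUE)
        logits <- matrix(fw$scores, cfg$L * B, cfg$nClasses)
        ce <- softmaxXent(logits, tgt, wt)
        dy <- array(ce$grad, dim = dim(fw$scores))
        bh <- netBackward(model$head, fw$headCaches, dy)
        bb <- netBackward(model$backbone, fw$backCaches, bh$dx)
        lr <- cdcLrAt(hyper, model$iterations)
        model$head <- sgdUpdate(model$head, bh$grads, state, lr,
                                hyper$momentum, hyper$weightDecay, "h", mth)
        model$backbone <- sgdUpdate(model$backbone, bb$grads, state, lr,
                                    hyper$momentum, hyper$weightDecay, "b", mth)
        state$step <- state$step + 1L
        model$iterations <- model$iterations + 1L
        epLoss <- epLoss + ce$loss; nb <- nb + 1L
      }
      model$history <- c(model$history, epLoss / nb)
      if (verbose)
        message(sprintf("cdc epoch %d: loss %.4f", ep, epLoss / nb))
    }
  })
  model
}

#' Per-frame prediction with the CDC scorer
#'
#' Runs the scorer over non-overlapping windows, drops padded frames, and
#' returns per-frame class probabilities, the argmax label track, and the
#' action segments obtained by grouping equal consecutive labels.
#'
#' @param model a trained \code{cdcModel}.
#' @param depth a \linkS4class{DepthSequence}.
#' @return list with \code{track} (\linkS4class{FrameLabelTrack}),
#'   \code{scores} ((K+1) x T matrix of probabilities, columns sum to 1)
#'   and \code{segments} (\linkS4class{ActionSegments}).
#' @export
predictFrames <- function(model, depth) {
  cfg <- model$config
  taxonomy <- actionTaxonomy()
  wins <- windowVideo(depth, cfg$L)
  B <- length(wins)
  x <- array(0, dim = c(cfg$inputSize, cfg$L, B, 1L))
  for (k in seq_len(B))
    x[, , , k, 1L] <- normalizeDepth(wins[[k]]$frames, cfg)
  fw <- cdcForward(model, x)
  probs <- softmaxRows(matrix(fw$scores, cfg$L * B, cfg$nClasses))
  T <- nFrames(depth)
  scores <- matrix(0, cfg$nClasses, T,
                   dimnames = list(taxonomy, NULL))
  for (k in seq_len(B)) {
    nValid <- sum(wins[[k]]$valid)
    rows <- (k - 1L) * cfg$L + seq_len(nValid)
    scores[, wins[[k]]$start + seq_len(nValid)] <- t(probs[rows, , drop = FALSE])
  }
  labels <- taxonomy[max.col(t(scores), ties.method = "first")]
  track <- FrameLabelTrack(labels)
  list(track = track, scores = scores, segments = segmentsFromTrack(track))
}
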