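## Label cleaning, multi-person filtering and class balancing applied to
## per-frame annotation tracks before training.

labelRuns <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  data.frame(start = end - r$lengths, end = end, label = r$values,
             stringsAsFactors = FALSE)
}

#' Clean a per-frame label track
#'
#' Applies the annotation rules used for training data: non-background runs
#' shorter than \code{minSeg} frames are relabeled as background (keeping the
#' stream aligned with its depth/skeleton frames), and background runs longer
#' than \code{bgCap} frames are truncated to their first \code{bgKeep} frames
#' (the remaining frames are dropped from the dataset view). The rule is a
#' strict inequality: a run of exactly \code{bgCap} frames is untouched.
#'
#' @param track a \linkS4class{FrameLabelTrack}.
#' @param minSeg minimum surviving action-run length, frames (default 5).
#' @param bgCap background run length above which truncation applies
#'   (default 150).
#' @param bgKeep frames kept from the head of an overlong background run
#'   (default 50).
#' @param minSegBackground also apply the short-run rule to background runs
#'   (default FALSE: it applies to action runs only).
#' @param returnIndex if TRUE, return \code{list(track, keep)} where
#'   \code{keep} maps the emitted frames to 1-based indices of the input.
#' @return a \linkS4class{FrameLabelTrack}, or a list when
#'   \code{returnIndex = TRUE}. \code{cleanTrack} is idempotent.
#' @examples
#' tr <- FrameLabelTrack(rep(c("none_of_the_above", "walking",
#'                             "none_of_the_above"), c(10, 3, 10)))
#' table(frameLabels(cleanTrack(tr)))  # 3-frame walking run removed
#' @export
cleanTrack <- function(track, minSeg = 5L, bgCap = 150L, bgKeep = 50L,
                       minSegBackground = FALSE, returnIndex = FALSE) {
  labels <- track@labels
  bg <- backgroundLabel()
  ## rule 1: short runs relabeled background
  runs <- labelRuns(labels)
  for (i in seq_len(nrow(runs))) {
    short <- (runs$end[i] - runs$start[i]) < minSeg
    applies <- runs$label[i] != bg || minSegBackground
    if (short && applies)
      labels[(runs$start[i] + 1L):runs$end[i]] <- bg
  }
  ## rule 2: overlong background runs truncated to their first bgKeep frames
  runs <- labelRuns(labels)
  keep <- logical(length(labels))
  for (i in seq_len(nrow(runs))) {
    idx <- (runs$start[i] + 1L):runs$end[i]
    if (runs$label[i] == bg && length(idx) > bgCap) {
      keep[idx[seq_len(bgKeep)]] <- TRUE
    } else keep[idx] <- TRUE
  }
  out <- FrameLabelTrack(labels[keep], track@personId[keep])
  if (returnIndex) list(track = out, keep = which(keep)) else out
}

#' Remove frames where several people are in view
#'
#' Frames in which two or more tracked bodies coexist are removed from all
#' modalities of the session; the survivors are re-packed contiguously and
#' the index map back to the original frames is returned. Surviving frames
#' are never reordered.
#'
#' @param session a \linkS4class{HomeSession}.
#' @return list with \code{session} (filtered \linkS4class{HomeSession};
#'   skeleton streams that lose all frames are dropped) and \code{keep}
#'   (1-based indices of surviving frames in the input).
#' @export
filterMultiperson <- function(session) {
  T <- nFrames(session)
  counts <- rowSums(vapply(session@skeletons, bodyPresent,
                           logical(T)))
  keep <- which(counts <= 1L)
  depth <- session@depth
  depth <- DepthSequence(depth@frames[, , keep, drop = FALSE],
                         timestamps = depth@timestamps[keep],
                         fps = depth@fps)
  skels <- lapply(session@skeletons, function(sk)
    SkeletonSequence(sk@joints[keep, , , drop = FALSE],
                     sk@joints2d[keep, , , drop = FALSE],
                     timestamps = sk@timestamps[keep], bodyId = sk@bodyId,
                     floorPlane = sk@floorPlane))
  present <- vapply(skels, function(sk) any(bodyPresent(sk)), logical(1))
  if (any(present)) skels <- skels[present] else skels <- skels[1L]
  track <- FrameLabelTrack(session@track@labels[keep],
                           session@track@personId[keep])
  list(session = HomeSession(depth, skels, track), keep = keep)
}

#' Convert between label tracks and action segments
#'
#' \code{segmentsFromTrack} groups maximal runs of equal labels into
#' segments tiling \code{[0, T)} with no gaps or overlaps (background runs
#' included). \code{trackFromSegments} paints segments onto a background
#' track of length \code{T}; when the segments tile the track the two are
#' exact inverses.
#'
#' @param track a \linkS4class{FrameLabelTrack}.
#' @param segments an \linkS4class{ActionSegments}.
#' @param T track length in frames.
#' @param score score assigned to emitted segments (default 1).
#' @return \code{segmentsFromTrack}: an \linkS4class{ActionSegments};
#'   \code{trackFromSegments}: a \linkS4class{FrameLabelTrack}.
#' @examples
#' tr <- FrameLabelTrack(c("walking", "walking", "none_of_the_above",
#'                         "reaching_forward"))
#' segmentTable(segmentsFromTrack(tr))
#' @export
segmentsFromTrack <- function(track, score = 1) {
  runs <- labelRuns(track@labels)
  ActionSegments(runs$start, runs$end, runs$label,
                 rep(score, nrow(runs)))
}

#' @rdname segmentsFromTrack
#' @export
trackFromSegments <- function(segments, T) {
  labels <- rep(backgroundLabel(), T)
  df <- segmentTable(segments)
  if (nrow(df)) {
    df <- df[order(df$score), , drop = FALSE]  # higher score painted last
    for (i in seq_len(nrow(df))) {
      a <- max(0L, floor(df$start[i])); b <- min(T, ceiling(df$end[i]))
      if (b > a) labels[(a + 1L):b] <- df$label[i]
    }
  }
  FrameLabelTrack(labels)
}

#' A labeled training clip
#'
#' One pre-segmented training example: the depth frames and/or skeleton
#' stream of a single action instance plus its class label.
#'
#' @param depth a \linkS4class{DepthSequence} or NULL.
#' @param skeleton a \linkS4class{SkeletonSequence} or NULL.
#' @param label the clip's class label.
#' @param augmented whether the clip was produced by augmentation.
#' @return list of class \code{actionClip}.
#' @export
actionClip <- function(depth = NULL, skeleton = NULL, label,
                       augmented = FALSE) {
  stopifnot(label %in% actionTaxonomy())
  structure(list(depth = depth, skeleton = skeleton, label = label,
                 augmented = augmented), class = "actionClip")
}

#' Cut a session into per-segment clips
#'
#' Slices all modalities of a session along the maximal label runs of its
#' track (ground truth or predictions) into \code{\link{actionClip}}s.
#'
#' @param session a \linkS4class{HomeSession}.
#' @param dropBackground omit background clips (default FALSE).
#' @return list of \code{actionClip}.
#' @export
extractClips <- function(session, dropBackground = FALSE) {
  df <- segmentTable(segmentsFromTrack(session@track))
  if (dropBackground) df <- df[df$label != backgroundLabel(), , drop = FALSE]
  prim <- session@skeletons[[1L]]
  lapply(seq_len(nrow(df)), function(i) {
    idx <- (df$start[i] + 1L):df$end[i]
    actionClip(
      depth = DepthSequence(session@depth@frames[, , idx, drop = FALSE],
                            fps = session@depth@fps),
      skeleton = SkeletonSequence(prim@joints[idx, , , drop = FALSE],
                                  prim@joints2d[idx, , , drop = FALSE],
                                  bodyId = prim@bodyId,
                                  floorPlane = prim@floorPlane),
      label = df$label[i])
  })
}

resampleDepth <- function(depth, Tnew) {
  Told <- dim(depth@frames)[3L]
  idx <- pmin(Told, pmax(1L, round(seq(1, Told, length.out = Tnew))))
  DepthSequence(depth@frames[, , idx, drop = FALSE], fps = depth@fps)
}

resampleSkeleton <- function(skel, Tnew) {
  Told <- dim(skel@joints)[1L]
  pos <- seq(1, Told, length.out = Tnew)
  S <- array(0, dim = c(Tnew, 19L, 3L))
  for (j in 1:19) for (d in 1:3)
    S[, j, d] <- approx(seq_len(Told), skel@joints[, j, d], xout = pos,
                        rule = 2)$y
  SkeletonSequence(S, bodyId = skel@bodyId, floorPlane = skel@floorPlane)
}

mirrorLR <- function() {
  jt <- jointTemplate()
  swapped <- sub("_l$", "_L", jt)
  swapped <- sub("_r$", "_l", swapped)
  swapped <- sub("_L$", "_r", swapped)
  match(swapped, jt)
}

#' Augment a training clip
#'
#' Applies label-preserving augmentations: temporal resampling within ±20%,
#' horizontal mirroring (depth frames flipped along the width; skeleton x
#' negated with left/right joints swapped, an involution), and additive
#' noise. By default one or more operations are drawn from the seed.
#'
#' @param clip an \code{\link{actionClip}}.
#' @param seed integer seed.
#' @param ops subset of \code{c("resample", "mirror", "noise")}; NULL draws
#'   a random non-empty subset.
#' @return an augmented \code{actionClip} (marked \code{augmented = TRUE}).
#' @export
augmentClip <- function(clip, seed = 0, ops = NULL) {
  stopifnot(inherits(clip, "actionClip"))
  withSeed(seed, {
    if (is.null(ops)) {
      all <- c("resample", "mirror", "noise")
      ops <- all[runif(3) < 0.5]
      if (!length(ops)) ops <- sample(all, 1)
    }
    if ("resample" %in% ops) {
      f <- runif(1, 0.8, 1.2)
      if (!is.null(clip$depth)) {
        Tnew <- max(2L, round(dim(clip$depth@frames)[3L] * f))
        clip$depth <- resampleDepth(clip$depth, Tnew)
      }
      if (!is.null(clip$skeleton)) {
        Tnew <- max(2L, round(dim(clip$skeleton@joints)[1L] * f))
        clip$skeleton <- resampleSkeleton(clip$skeleton, Tnew)
      }
    }
    if ("mirror" %in% ops) {
      if (!is.null(clip$depth))
        clip$depth@frames <- clip$depth@frames[, dim(clip$depth@frames)[2L]:1, ,
                                               drop = FALSE]
      if (!is.null(clip$skeleton)) {
        S <- clip$skeleton@joints[, mirrorLR(), , drop = FALSE]
        S[, , 1L] <- -S[, , 1L]
        clip$skeleton@joints <- S
      }
    }
    if ("noise" %in% ops) {
      if (!is.null(clip$depth)) {
        fr <- clip$depth@frames
        fr[] <- as.integer(pmax(0, round(fr + rnorm(length(fr), 0, 10))))
        clip$depth@frames <- fr
      }
      if (!is.null(clip$skeleton))
        clip$skeleton@joints <- clip$skeleton@joints +
          array(rnorm(length(clip$skeleton@joints), 0, 0.005),
                dim = dim(clip$skeleton@joints))
    }
  })
  clip$augmented <- TRUE
  clip
}

#' Balance a clip dataset across classes
#'
#' Augments under-represented action classes up to at least half of the
#' largest action-class count (so the spread across action classes is at
#' most 2:1) and down-samples the background class to at most the largest
#' action-class count. Augmented clips are marked; selection is seeded and
#' reproducible.
#'
#' @param clips list of \code{\link{actionClip}}.
#' @param seed integer seed.
#' @return list of \code{actionClip}.
#' @export
balanceDataset <- function(clips, seed = 0) {
  labels <- vapply(clips, `[[`, "", "label")
  bg <- backgroundLabel()
  counts <- table(factor(labels, levels = actionTaxonomy()))
  actionMax <- max(c(0L, counts[setdiff(actionTaxonomy(), bg)]))
  target <- ceiling(actionMax / 2)
  out <- clips
  withSeed(seed, {
    for (cl in setdiff(actionTaxonomy(), bg)) {
      have <- which(labels == cl)
      n <- length(have)
      if (n > 0L && n < target) {
        src <- rep(have, length.out = target - n)
        for (k in seq_along(src))
          out[[length(out) + 1L]] <- augmentClip(clips[[src[k]]],
                                                 seed = seed + 7L * k)
      }
    }
    bgIdx <- which(vapply(out, `[[`, "", "label") == bg)
    if (length(bgIdx) > actionMax) {
      dropN <- length(bgIdx) - actionMax
      drop <- sample(bgIdx, dropN)
      out <- out[-drop]
    }
  })
  out
}
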