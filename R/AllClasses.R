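#' @import methods
NULL

#' Action taxonomy for in-home activity monitoring
#'
#' The six per-frame label categories used throughout the package: five
#' clinically relevant action classes plus a background class
#' (\code{"none_of_the_above"}) that absorbs idle frames and frames where
#' several actions are performed simultaneously.
#'
#' @return Character vector of length 6, background last.
#' @examples
#' actionTaxonomy()
#' @export
actionTaxonomy <- function() {
  c("walking", "reaching_overhead", "reaching_forward",
    "reaching_below_waist", "hand_manipulation", "none_of_the_above")
}

#' @rdname actionTaxonomy
#' @export
backgroundLabel <- function() "none_of_the_above"

#' @rdname actionTaxonomy
#' @export
nActionClasses <- function() length(actionTaxonomy()) - 1L

#' The 19-joint skeleton template
#'
#' Joint names, in stream order, for the 19-joint skeletons emitted by the
#' depth sensor's body tracker. The naming is a package convention; only the
#' joint count is fixed by the sensor.
#'
#' @return Character vector of length 19.
#' @export
jointTemplate <- function() {
  c("head", "neck", "torso", "waist", "mid_hip",
    "shoulder_l", "shoulder_r", "elbow_l", "elbow_r",
    "wrist_l", "wrist_r", "hand_l", "hand_r",
    "hip_l", "hip_r", "knee_l", "knee_r", "foot_l", "foot_r")
}

## ---- DepthSequence ---------------------------------------------------------

#' DepthSequence: a stack of millimeter depth frames
#'
#' Container for a depth video: an H x W x T array of non-negative integer
#' millimeter depths plus strictly increasing per-frame timestamps.
#'
#' @slot frames integer array, dim c(H, W, T), depths in millimeters.
#' @slot timestamps numeric length T, seconds, strictly increasing.
#' @slot fps numeric scalar, nominal frame rate.
#' @export
setClass("DepthSequence",
  representation(frames = "array", timestamps = "numeric", fps = "numeric"))

setValidity("DepthSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (any(object@frames < 0, na.rm = TRUE)) return("depth values must be >= 0")
  if (length(object@timestamps) != d[3L])
    return("timestamps length must equal frame count")
  if (d[3L] > 1L && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  TRUE
})

#' Construct a DepthSequence
#'
#' @param frames H x W x T numeric array of millimeter depths (a single H x W
#'   matrix is promoted to T = 1).
#' @param timestamps optional numeric vector of length T; defaults to a
#'   uniform clock at \code{fps}.
#' @param fps nominal frame rate in Hz; the logger's achieved rate of 8 fps is
#'   the default.
#' @return A \linkS4class{DepthSequence}.
#' @examples
#' d <- DepthSequence(array(1200L, dim = c(4, 4, 3)))
#' nFrames(d)
#' @export
DepthSequence <- function(frames, timestamps = NULL, fps = 8) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  dimnames(frames) <- NULL
  if (is.null(timestamps)) timestamps <- (seq_len(dim(frames)[3L]) - 1) / fps
  new("DepthSequence", frames = frames, timestamps = as.numeric(timestamps),
      fps = as.numeric(fps))
}

## ---- SkeletonSequence ------------------------------------------------------

#' SkeletonSequence: a per-frame 19-joint 3D pose stream for one body
#'
#' @slot joints numeric array, dim c(T, 19, 3), meters.
#' @slot joints2d numeric array, dim c(T, 19, 2), pixels (may be all NA).
#' @slot timestamps numeric length T, seconds.
#' @slot bodyId integer in [0, 5), the tracker's body index.
#' @slot floorPlane numeric length 4, plane coefficients (ax+by+cz+d=0).
#' @export
setClass("SkeletonSequence",
  representation(joints = "array", joints2d = "array", timestamps = "numeric",
                 bodyId = "integer", floorPlane = "numeric"))

setValidity("SkeletonSequence", function(object) {
  d <- dim(object@joints)
  if (length(d) != 3L || d[2L] != 19L || d[3L] != 3L)
    return("joints must be a T x 19 x 3 array")
  d2 <- dim(object@joints2d)
  if (length(d2) != 3L || d2[1L] != d[1L] || d2[2L] != 19L || d2[3L] != 2L)
    return("joints2d must be a T x 19 x 2 array")
  if (length(object@timestamps) != d[1L])
    return("timestamps length must equal T")
  if (object@bodyId < 0L || object@bodyId >= 5L)
    return("bodyId must lie in [0, 5)")
  if (length(object@floorPlane) != 4L)
    return("floorPlane must have 4 coefficients")
  TRUE
})

#' Construct a SkeletonSequence
#'
#' @param joints T x 19 x 3 array of 3D joint coordinates, meters.
#' @param joints2d optional T x 19 x 2 array of image-plane projections.
#' @param timestamps optional numeric length T; defaults to a uniform clock.
#' @param bodyId tracker body index in [0, 5).
#' @param floorPlane 4 plane coefficients; default is a z-up floor at 0.
#' @param fps frame rate used for the default clock.
#' @return A \linkS4class{SkeletonSequence}.
#' @export
SkeletonSequence <- function(joints, joints2d = NULL, timestamps = NULL,
                             bodyId = 0L, floorPlane = c(0, 0, 1, 0), fps = 8) {
  T <- dim(joints)[1L]
  dimnames(joints) <- list(NULL, jointTemplate(), c("x", "y", "z"))
  if (is.null(joints2d)) joints2d <- array(NA_real_, dim = c(T, 19L, 2L))
  dimnames(joints2d) <- NULL
  if (is.null(timestamps)) timestamps <- (seq_len(T) - 1) / fps
  new("SkeletonSequence", joints = joints, joints2d = joints2d,
      timestamps = as.numeric(timestamps), bodyId = as.integer(bodyId),
      floorPlane = as.numeric(floorPlane))
}

## ---- FrameLabelTrack -------------------------------------------------------

#' FrameLabelTrack: per-frame action labels
#'
#' @slot labels character vector over \code{actionTaxonomy()}.
#' @slot personId integer vector (NA when unassigned), one entry per frame.
#' @export
setClass("FrameLabelTrack",
  representation(labels = "character", personId = "integer"))

setValidity("FrameLabelTrack", function(object) {
  if (!all(object@labels %in% actionTaxonomy()))
    return("all labels must belong to actionTaxonomy()")
  if (length(object@personId) != length(object@labels))
    return("personId length must equal labels length")
  TRUE
})

#' Construct a FrameLabelTrack
#'
#' @param labels character vector of per-frame labels over
#'   \code{actionTaxonomy()}.
#' @param personId optional integer vector of per-frame person ids.
#' @return A \linkS4class{FrameLabelTrack}.
#' @examples
#' FrameLabelTrack(rep(c("walking", "none_of_the_above"), c(3, 2)))
#' @export
FrameLabelTrack <- function(labels, personId = NULL) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.null(personId)) personId <- rep(NA_integer_, length(labels))
  new("FrameLabelTrack", labels = labels, personId = as.integer(personId))
}

## ---- ActionSegments --------------------------------------------------------

#' ActionSegments: labeled half-open frame intervals
#'
#' A set of action instances, each a half-open frame interval [start, end)
#' in 0-based frame coordinates with a class label, a confidence score and an
#' optional person id. The center/length parameterization used by anchor
#' regression is \code{center = (start + end) / 2}, \code{length = end - start}.
#'
#' @slot segments data.frame with columns start, end, label, score, personId.
#' @export
setClass("ActionSegments", representation(segments = "data.frame"))

setValidity("ActionSegments", function(object) {
  df <- object@segments
  need <- c("start", "end", "label", "score", "personId")
  if (!identical(names(df), need))
    return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
  if (nrow(df) && any(df$end <= df$start))
    return("segments must satisfy start < end (non-empty half-open intervals)")
  TRUE
})

#' Construct ActionSegments
#'
#' @param start,end 0-based half-open frame bounds, \code{start < end}.
#' @param label character labels over \code{actionTaxonomy()}.
#' @param score confidence in [0, 1]; defaults to 1.
#' @param personId optional integer person ids.
#' @return An \linkS4class{ActionSegments}.
#' @examples
#' ActionSegments(0, 10, "walking")
#' @export
ActionSegments <- function(start = numeric(0), end = numeric(0),
                           label = character(0), score = NULL,
                           personId = NULL) {
  n <- length(start)
  if (is.null(score)) score <- rep(1, n)
  if (is.null(personId)) personId <- rep(NA_integer_, n)
  new("ActionSegments", segments = data.frame(
    start = as.numeric(start), end = as.numeric(end),
    label = as.character(label), score = as.numeric(score),
    personId = as.integer(personId), stringsAsFactors = FALSE))
}

## ---- HomeSession ------------------------------------------------------------

#' HomeSession: one recorded (or simulated) session
#'
#' Bundles the three per-frame modalities of one monitoring session: the
#' depth video, one or more skeleton streams (one per tracked body), and the
#' ground-truth or predicted label track. All modalities share the frame axis.
#'
#' @slot depth a \linkS4class{DepthSequence}.
#' @slot skeletons list of \linkS4class{SkeletonSequence}, one per body.
#' @slot track a \linkS4class{FrameLabelTrack}.
#' @export
setClass("HomeSession",
  representation(depth = "DepthSequence", skeletons = "list",
                 track = "FrameLabelTrack"))

setValidity("HomeSession", function(object) {
  T <- dim(object@depth@frames)[3L]
  if (length(object@track@labels) != T)
    return("track length must equal depth frame count")
  for (sk in object@skeletons) {
    if (!is(sk, "SkeletonSequence")) return("skeletons must be SkeletonSequence")
    if (dim(sk@joints)[1L] != T)
      return("every skeleton stream must have one record per frame")
  }
  TRUE
})

#' Construct a HomeSession
#'
#' @param depth a \linkS4class{DepthSequence}.
#' @param skeletons a \linkS4class{SkeletonSequence} or list of them.
#' @param track a \linkS4class{FrameLabelTrack}.
#' @return A \linkS4class{HomeSession}.
#' @export
HomeSession <- function(depth, skeletons, track) {
  if (is(skeletons, "SkeletonSequence")) skeletons <- list(skeletons)
  new("HomeSession", depth = depth, skeletons = skeletons, track = track)
}
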