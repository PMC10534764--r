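#' Number of frames
#'
#' @param x a DepthSequence, SkeletonSequence, FrameLabelTrack, or HomeSession.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "DepthSequence", function(x) dim(x@frames)[3L])
#' @rdname nFrames
#' @export
setMethod("nFrames", "SkeletonSequence", function(x) dim(x@joints)[1L])
#' @rdname nFrames
#' @export
setMethod("nFrames", "FrameLabelTrack", function(x) length(x@labels))
#' @rdname nFrames
#' @export
setMethod("nFrames", "HomeSession", function(x) nFrames(x@depth))

#' Accessors for the core containers
#'
#' \code{depthFrames} returns the H x W x T millimeter array;
#' \code{frameTimestamps} the per-frame clock; \code{joints3d} the T x 19 x 3
#' joint array; \code{bodyId} the tracker body index; \code{frameLabels} the
#' per-frame label vector; \code{segmentTable} the segment data.frame.
#'
#' @param x an object of the matching class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
depthFrames <- function(x) x@frames

#' @rdname accessors
#' @export
frameTimestamps <- function(x) x@timestamps

#' @rdname accessors
#' @export
joints3d <- function(x) x@joints

#' @rdname accessors
#' @export
bodyId <- function(x) x@bodyId

#' @rdname accessors
#' @export
frameLabels <- function(x) {
  if (is(x, "HomeSession")) x@track@labels else x@labels
}

#' @rdname accessors
#' @export
segmentTable <- function(x) x@segments

#' @rdname accessors
#' @export
sessionDepth <- function(x) x@depth

#' @rdname accessors
#' @export
sessionSkeletons <- function(x) x@skeletons

#' @rdname accessors
#' @export
sessionTrack <- function(x) x@track

setMethod("show", "DepthSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("DepthSequence: %d frames of %dx%d px, %.3g-%.3g mm, %.3g fps\n",
              d[3L], d[1L], d[2L], min(object@frames), max(object@frames),
              object@fps))
})

setMethod("show", "SkeletonSequence", function(object) {
  cat(sprintf("SkeletonSequence: body %d, %d frames x 19 joints\n",
              object@bodyId, nFrames(object)))
})

setMethod("show", "FrameLabelTrack", function(object) {
  tb <- table(factor(object@labels, levels = actionTaxonomy()))
  cat(sprintf("FrameLabelTrack: %d frames (%s)\n", length(object@labels),
              paste(sprintf("%s:%d", names(tb)[tb > 0], tb[tb > 0]),
                    collapse = ", ")))
})

setMethod("show", "ActionSegments", function(object) {
  cat(sprintf("ActionSegments: %d segments\n", nrow(object@segments)))
  if (nrow(object@segments)) print(utils::head(object@segments, 10))
})

setMethod("show", "HomeSession", function(object) {
  cat(sprintf("HomeSession: %d frames, %d skeleton stream(s)\n",
              nFrames(object), length(object@skeletons)))
})

#' Length of an ActionSegments set
#' @param x an ActionSegments.
#' @export
setMethod("length", "ActionSegments", function(x) nrow(x@segments))
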