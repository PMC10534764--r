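## End-to-end orchestration: simulate -> prep -> train (three detectors) ->
## detect -> fuse -> evaluate, with a single seed controlling every source
## of randomness.

#' Pipeline run configuration
#'
#' All thresholds and module configurations referenced anywhere in the
#' pipeline live here with their defaults. Unknown keys are rejected with
#' the list of valid ones.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param profile hyperparameter profile name ("desk" or "paper").
#' @param nTrain,nTest number of synthetic training / held-out sessions.
#' @param noise generator noise model (\code{\link{synthNoise}}).
#' @param camera generator camera (\code{\link{synthCamera}}).
#' @param cdc,rc3d,rhcn module configurations.
#' @param minPredSeg minimum length (frames) of predicted action runs kept
#'   in the fused track; shorter runs revert to background, mirroring the
#'   annotation convention.
#' @param iouThr per-action evaluation threshold.
#' @param outDir artifact directory or NULL.
#' @param verbose log stage progress and filter counts.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(seed = 0L, profile = "desk", nTrain = 200L,
                      nTest = 50L, noise = synthNoise(),
                      camera = synthCamera(), cdc = cdcDeskConfig(),
                      rc3d = rc3dConfig(scoreThr = 0.3), rhcn = rhcnConfig(),
                      minPredSeg = 5L, iouThr = 0.5, outDir = NULL,
                      verbose = FALSE) {
  structure(list(seed = as.integer(seed), profile = profile,
                 nTrain = as.integer(nTrain), nTest = as.integer(nTest),
                 noise = noise, camera = camera, cdc = cdc, rc3d = rc3d,
                 rhcn = rhcn, minPredSeg = as.integer(minPredSeg),
                 iouThr = iouThr, outDir = outDir, verbose = verbose),
            class = "runConfig")
}

#' Validate a configuration key list
#'
#' @param keys named list (e.g. parsed from a YAML config file).
#' @return a \code{runConfig} built from the keys.
#' @export
validateConfig <- function(keys) {
  valid <- names(formals(runConfig))
  bad <- setdiff(names(keys), valid)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; valid keys are: ", paste(valid, collapse = ", "))
  do.call(runConfig, keys)
}

## drop sub-minimum action runs from a predicted track (the background cap
## is disabled: Inf never truncates)
smoothPredictedTrack <- function(track, minSeg) {
  cleanTrack(track, minSeg = minSeg, bgCap = Inf)
}

## offset a segment table by a frame shift (for pooling sessions)
shiftSegments <- function(df, off) {
  if (nrow(df)) {
    df$start <- df$start + off
    df$end <- df$end + off
  }
  df
}

#' Run the full recognition pipeline
#'
#' Simulates training and held-out sessions, applies the annotation
#' preparation rules, trains the three detectors, predicts per-frame
#' tracks on the held-out sessions, fuses them by the two-vote rule, and
#' evaluates per-frame and per-action precision against ground truth.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list of class \code{pipelineResult}: \code{fused}
#'   (a \code{metricsReport}), per-network reports (\code{cdc},
#'   \code{rc3d}, \code{rhcn}), the trained \code{models}, and the
#'   held-out \code{sessions} with their fused tracks.
#' @export
runPipeline <- function(config = runConfig()) {
  stopifnot(inherits(config, "runConfig"))
  vlog <- function(...) if (config$verbose) message(sprintf(...))
  hyper <- hyperProfile(config$profile)
  vlog("simulating %d training and %d held-out sessions",
       config$nTrain, config$nTest)
  train <- simulateSessions(config$nTrain, seed = config$seed,
                            noise = config$noise, camera = config$camera)
  test <- simulateSessions(config$nTest, seed = config$seed + 500000L,
                           noise = config$noise, camera = config$camera)
  ## annotation preparation on the training tracks
  nShort <- 0L; nMulti <- 0L
  train <- lapply(train, function(s) {
    flt <- filterMultiperson(s)
    nMulti <<- nMulti + (nFrames(s) - length(flt$keep))
    s <- flt$session
    cleaned <- cleanTrack(sessionTrack(s), returnIndex = TRUE)
    nShort <<- nShort + (nFrames(s) - length(cleaned$keep))
    if (length(cleaned$keep) < nFrames(s)) {
      dp <- DepthSequence(depthFrames(sessionDepth(s))[, , cleaned$keep,
                                                       drop = FALSE],
                          fps = sessionDepth(s)@fps)
      sk <- lapply(sessionSkeletons(s), function(x)
        SkeletonSequence(x@joints[cleaned$keep, , , drop = FALSE],
                         bodyId = x@bodyId))
      s <- HomeSession(dp, sk, cleaned$track)
    } else {
      s <- HomeSession(sessionDepth(s), sessionSkeletons(s), cleaned$track)
    }
    s
  })
  vlog("prep: %d multi-person frames removed, %d frames dropped by track cleaning",
       nMulti, nShort)
  vlog("training per-frame scorer (CDC)")
  cdcModel <- buildCdc(config$cdc, seed = config$seed + 1L)
  cdcModel <- trainCdc(cdcModel, train, hyper$cdc, seed = config$seed + 2L,
                       verbose = config$verbose)
  vlog("training depth segment detector (R-C3D)")
  rc3dModel <- buildRc3d(config$rc3d, seed = config$seed + 3L)
  rc3dModel <- trainRc3d(rc3dModel, train, hyper$rc3d,
                         seed = config$seed + 4L, verbose = config$verbose)
  vlog("training skeleton detector (RHCN)")
  rhcnModel <- buildRhcn(config$rhcn, seed = config$seed + 5L)
  rhcnModel <- trainRhcn(rhcnModel, train, hyper$rhcn,
                         seed = config$seed + 6L, verbose = config$verbose)
  vlog("detecting and fusing on %d held-out sessions", length(test))
  gtLabels <- character(0)
  netLabels <- list(cdc = character(0), rc3d = character(0),
                    rhcn = character(0), fused = character(0))
  pooled <- list(fused = NULL, cdc = NULL, rc3d = NULL, rhcn = NULL,
                 gt = NULL)
  off <- 0
  fusedTracks <- vector("list", length(test))
  for (i in seq_along(test)) {
    s <- test[[i]]
    T <- nFrames(s)
    pCdc <- predictFrames(cdcModel, sessionDepth(s))
    dRc <- detectRc3d(rc3dModel, sessionDepth(s))
    dRh <- detectRhcn(rhcnModel, sessionSkeletons(s)[[1L]])
    fused <- fuseFrameVotes(pCdc$track, dRc$track, dRh$track)
    fused <- smoothPredictedTrack(fused, config$minPredSeg)
    fusedTracks[[i]] <- fused
    gtLabels <- c(gtLabels, frameLabels(s))
    netLabels$cdc <- c(netLabels$cdc, frameLabels(pCdc$track))
    netLabels$rc3d <- c(netLabels$rc3d, frameLabels(dRc$track))
    netLabels$rhcn <- c(netLabels$rhcn, frameLabels(dRh$track))
    netLabels$fused <- c(netLabels$fused, frameLabels(fused))
    pooled$gt <- rbind(pooled$gt,
                       shiftSegments(segmentTable(
                         segmentsFromTrack(sessionTrack(s))), off))
    pooled$fused <- rbind(pooled$fused,
                          shiftSegments(segmentTable(
                            segmentsFromTrack(fused)), off))
    pooled$cdc <- rbind(pooled$cdc,
                        shiftSegments(segmentTable(
                          smoothedSegments(pCdc$track, config$minPredSeg)),
                          off))
    pooled$rc3d <- rbind(pooled$rc3d,
                         shiftSegments(segmentTable(dRc$segments), off))
    pooled$rhcn <- rbind(pooled$rhcn,
                         shiftSegments(segmentTable(dRh$segments), off))
    off <- off + T
  }
  asSegs <- function(df) {
    if (is.null(df) || !nrow(df)) return(ActionSegments())
    ActionSegments(df$start, df$end, df$label, df$score, df$personId)
  }
  gtSegs <- asSegs(pooled$gt)
  reports <- list(
    fused = metricsReport(netLabels$fused, gtLabels,
                          asSegs(pooled$fused), gtSegs, config$iouThr),
    cdc = metricsReport(netLabels$cdc, gtLabels, asSegs(pooled$cdc),
                        gtSegs, config$iouThr),
    rc3d = metricsReport(netLabels$rc3d, gtLabels, asSegs(pooled$rc3d),
                         gtSegs, config$iouThr),
    rhcn = metricsReport(netLabels$rhcn, gtLabels, asSegs(pooled$rhcn),
                         gtSegs, config$iouThr))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(test))
      writeLabelTrack(fusedTracks[[i]],
                      file.path(config$outDir,
                                sprintf("fused_%03d.tsv", i)))
    manifest <- list(seed = config$seed, profile = config$profile,
                     nTrain = config$nTrain, nTest = config$nTest,
                     perFramePrecision = reports$fused$perFramePrecision,
                     perActionPrecision = reports$fused$perActionPrecision)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(fused = reports$fused, cdc = reports$cdc,
                 rc3d = reports$rc3d, rhcn = reports$rhcn,
                 models = list(cdc = cdcModel, rc3d = rc3dModel,
                               rhcn = rhcnModel),
                 fusedTracks = fusedTracks, testSessions = test),
            class = "pipelineResult")
}

smoothedSegments <- function(track, minSeg) {
  segmentsFromTrack(smoothPredictedTrack(track, minSeg))
}

#' @export
print.pipelineResult <- function(x, ...) {
  cat("pipeline result (fused ensemble):\n")
  print(x$fused)
  cat(sprintf("\nsingle networks, per-frame precision: cdc %.3f, rc3d %.3f, rhcn %.3f\n",
              x$cdc$perFramePrecision, x$rc3d$perFramePrecision,
              x$rhcn$perFramePrecision))
  invisible(x)
}
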