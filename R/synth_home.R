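## Synthetic home-session generator: kinematic 19-joint trajectories for the
## six label classes, a capsule-based depth renderer, and session assembly
## with per-frame ground truth. Stands in for private in-home recordings so
## the full pipeline is testable end to end.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Noise model for the synthetic generator
#'
#' @param depthSigma additive depth noise, millimeters (sd).
#' @param jointSigma additive joint coordinate noise, meters (sd).
#' @param dropout per-joint per-frame probability of a tracking dropout
#'   (joint reported missing).
#' @return list of class \code{synthNoise}.
#' @export
synthNoise <- function(depthSigma = 15, jointSigma = 0.008, dropout = 0.01) {
  structure(list(depthSigma = depthSigma, jointSigma = jointSigma,
                 dropout = dropout), class = "synthNoise")
}

#' Synthetic camera model
#'
#' A pinhole camera giving the side view the sensor installation aims for:
#' mounted at chest height, looking horizontally at the work area. World
#' coordinates: x lateral, y distance from the camera plane, z up; the
#' reported depth of a surface point is its y distance in millimeters.
#'
#' @param width,height image size in pixels.
#' @param focal focal length in pixels.
#' @param cameraHeight mount height above the floor, meters.
#' @param backgroundDepth constant background-plane depth, millimeters.
#' @return list of class \code{synthCamera}.
#' @export
synthCamera <- function(width = 28L, height = 28L, focal = width * 1.8,
                        cameraHeight = 1.2, backgroundDepth = 4000) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 fx = focal, fy = focal, cx = (width + 1) / 2,
                 cy = (height + 1) / 2, cameraHeight = cameraHeight,
                 backgroundDepth = backgroundDepth), class = "synthCamera")
}

## Rest pose: standing at lateral offset x0, distance y0 from the camera.
## Columns x (lateral, m), y (depth, m), z (height above floor, m).
restPose <- function(x0 = 0, y0 = 2.5) {
  J <- matrix(0, 19L, 3L, dimnames = list(jointTemplate(), c("x", "y", "z")))
  z <- c(head = 1.60, neck = 1.45, torso = 1.28, waist = 1.10,
         mid_hip = 0.95,
         shoulder_l = 1.40, shoulder_r = 1.40, elbow_l = 1.15, elbow_r = 1.15,
         wrist_l = 0.90, wrist_r = 0.90, hand_l = 0.82, hand_r = 0.82,
         hip_l = 0.92, hip_r = 0.92, knee_l = 0.50, knee_r = 0.50,
         foot_l = 0.05, foot_r = 0.05)
  xl <- c(head = 0, neck = 0, torso = 0, waist = 0, mid_hip = 0,
          shoulder_l = -0.20, shoulder_r = 0.20, elbow_l = -0.25,
          elbow_r = 0.25, wrist_l = -0.28, wrist_r = 0.28,
          hand_l = -0.29, hand_r = 0.29, hip_l = -0.12,
          hip_r = 0.12, knee_l = -0.12, knee_r = 0.12, foot_l = -0.12,
          foot_r = 0.12)
  J[, "x"] <- x0 + xl[jointTemplate()]
  J[, "y"] <- y0
  J[, "z"] <- z[jointTemplate()]
  J
}

## Unimodal raise-then-lower profile: 0 at both ends, 1 at the midpoint.
reachProfile <- function(n) sin(pi * (seq_len(n) - 1) / (n - 1))

## Deterministic trajectory for one action class (no noise): T x 19 x 3.
actionTrajectory <- function(label, n) {
  base <- restPose()
  S <- array(rep(base, each = n), dim = c(n, 19L, 3L),
             dimnames = list(NULL, jointTemplate(), c("x", "y", "z")))
  p <- (seq_len(n) - 1) / (n - 1)
  arm <- c("shoulder_r", "elbow_r", "wrist_r", "hand_r")
  b <- reachProfile(n)
  if (label == "walking") {
    ## out-and-back lateral translation of the whole body, small leg swing
    dx <- 0.8 * sin(2 * pi * p)
    S[, , "x"] <- S[, , "x"] + dx
    swing <- 0.12 * sin(2 * pi * p * max(2, round(n / 10)))
    for (j in c("knee_l", "foot_l")) S[, j, "y"] <- S[, j, "y"] + swing
    for (j in c("knee_r", "foot_r")) S[, j, "y"] <- S[, j, "y"] - swing
  } else if (label == "reaching_overhead") {
    S[, "wrist_r", "z"] <- S[, "wrist_r", "z"] + 0.85 * b
    S[, "hand_r", "z"] <- S[, "hand_r", "z"] + 0.88 * b
    S[, "elbow_r", "z"] <- S[, "elbow_r", "z"] + 0.45 * b
    S[, arm, "x"] <- S[, arm, "x"] - outer(0.12 * b, rep(1, 4))
  } else if (label == "reaching_forward") {
    S[, "wrist_r", "y"] <- S[, "wrist_r", "y"] - 0.45 * b
    S[, "hand_r", "y"] <- S[, "hand_r", "y"] - 0.48 * b
    S[, "elbow_r", "y"] <- S[, "elbow_r", "y"] - 0.25 * b
    S[, "wrist_r", "z"] <- S[, "wrist_r", "z"] + 0.50 * b
    S[, "hand_r", "z"] <- S[, "hand_r", "z"] + 0.50 * b
    S[, "elbow_r", "z"] <- S[, "elbow_r", "z"] + 0.25 * b
  } else if (label == "reaching_below_waist") {
    S[, "wrist_r", "z"] <- S[, "wrist_r", "z"] - 0.55 * b
    S[, "hand_r", "z"] <- S[, "hand_r", "z"] - 0.57 * b
    S[, "elbow_r", "z"] <- S[, "elbow_r", "z"] - 0.30 * b
    S[, c("head", "neck", "torso"), "y"] <-
      S[, c("head", "neck", "torso"), "y"] - outer(0.10 * b, rep(1, 3))
  } else if (label == "hand_manipulation") {
    osc <- sin(2 * pi * p * max(3, round(n / 8)))
    S[, "wrist_r", "y"] <- S[, "wrist_r", "y"] - 0.20 - 0.04 * osc
    S[, "hand_r", "y"] <- S[, "hand_r", "y"] - 0.22 - 0.05 * osc
    S[, "wrist_r", "z"] <- S[, "wrist_r", "z"] + 0.25 + 0.03 * osc
    S[, "hand_r", "z"] <- S[, "hand_r", "z"] + 0.25 + 0.04 * osc
    S[, "elbow_r", "y"] <- S[, "elbow_r", "y"] - 0.10
  } else if (label == "none_of_the_above") {
    ## idle: rest pose with barely perceptible sway
    S[, , "x"] <- S[, , "x"] + 0.005 * sin(2 * pi * p)
  } else {
    stop("unknown action label: ", label)
  }
  S
}

#' Generate one labeled skeleton clip
#'
#' Produces a deterministic 19-joint kinematic trajectory for one action
#' class plus its constant ground-truth label track. Reaching classes follow
#' the raise-then-lower convention: the wrist profile is unimodal and the
#' pose starts and ends at rest. Walking translates the root laterally;
#' hand manipulation keeps wrist displacements small-amplitude; the
#' background class is idle.
#'
#' @param label one of \code{actionTaxonomy()}.
#' @param nFrames number of frames (>= 5).
#' @param noise a \code{\link{synthNoise}} model.
#' @param seed integer seed; same arguments and seed give identical output.
#' @param fps frame rate, Hz.
#' @return list with elements \code{skeleton} (a
#'   \linkS4class{SkeletonSequence}; dropout joints are NA) and \code{track}
#'   (a \linkS4class{FrameLabelTrack}).
#' @examples
#' clip <- makeSkeletonClip("reaching_overhead", 30, synthNoise(0, 0, 0), 1)
#' max(joints3d(clip$skeleton)[, "wrist_r", "z"])
#' @export
makeSkeletonClip <- function(label, nFrames, noise = synthNoise(), seed = 0,
                             fps = 8) {
  if (!label %in% actionTaxonomy())
    stop("unknown action label: ", label, " (see actionTaxonomy())")
  if (nFrames < 5L) stop("nFrames must be at least 5")
  S <- actionTrajectory(label, nFrames)
  withSeed(seed, {
    if (noise$jointSigma > 0)
      S <- S + array(rnorm(length(S), 0, noise$jointSigma), dim = dim(S))
    if (noise$dropout > 0) {
      drop <- matrix(runif(nFrames * 19L) < noise$dropout, nFrames, 19L)
      for (t in seq_len(nFrames)) S[t, drop[t, ], ] <- NA_real_
    }
  })
  list(skeleton = SkeletonSequence(S, fps = fps),
       track = FrameLabelTrack(rep(label, nFrames)))
}

#' Impute missing joints by linear interpolation over time
#'
#' Tracking dropouts (NA joints) are filled per joint and axis by linear
#' interpolation between the nearest observed frames (constant extrapolation
#' at the ends).
#'
#' @param skeleton a \linkS4class{SkeletonSequence}.
#' @return a \linkS4class{SkeletonSequence} without missing joints.
#' @export
imputeJoints <- function(skeleton) {
  S <- skeleton@joints
  T <- dim(S)[1L]
  for (j in seq_len(19L)) for (d in 1:3) {
    v <- S[, j, d]
    if (anyNA(v) && any(!is.na(v))) {
      S[, j, d] <- approx(which(!is.na(v)), v[!is.na(v)], xout = seq_len(T),
                          rule = 2)$y
    }
  }
  skeleton@joints <- S
  skeleton
}

## Bones (joint index pairs) and capsule radii (m) for rendering.
synthBones <- function() {
  jt <- jointTemplate()
  idx <- function(a, b) c(match(a, jt), match(b, jt))
  list(
    list(idx("head", "neck"), 0.10), list(idx("neck", "torso"), 0.13),
    list(idx("torso", "waist"), 0.14), list(idx("waist", "mid_hip"), 0.14),
    list(idx("neck", "shoulder_l"), 0.06), list(idx("neck", "shoulder_r"), 0.06),
    list(idx("shoulder_l", "elbow_l"), 0.05), list(idx("shoulder_r", "elbow_r"), 0.05),
    list(idx("elbow_l", "wrist_l"), 0.045), list(idx("elbow_r", "wrist_r"), 0.045),
    list(idx("wrist_l", "hand_l"), 0.05), list(idx("wrist_r", "hand_r"), 0.05),
    list(idx("mid_hip", "hip_l"), 0.09), list(idx("mid_hip", "hip_r"), 0.09),
    list(idx("hip_l", "knee_l"), 0.07), list(idx("hip_r", "knee_r"), 0.07),
    list(idx("knee_l", "foot_l"), 0.06), list(idx("knee_r", "foot_r"), 0.06))
}

renderOneFrame <- function(J, camera) {
  depth <- matrix(camera$backgroundDepth, camera$height, camera$width)
  pts <- NULL
  for (bn in synthBones()) {
    a <- J[bn[[1]][1L], ]; b <- J[bn[[1]][2L], ]; r <- bn[[2]]
    if (anyNA(a) || anyNA(b)) next
    len <- sqrt(sum((b - a)^2))
    k <- max(2L, ceiling(len / 0.05) + 1L)
    s <- (seq_len(k) - 1) / (k - 1)
    x <- (1 - s) * a[1L] + s * b[1L]
    y <- (1 - s) * a[2L] + s * b[2L]
    z <- (1 - s) * a[3L] + s * b[3L]
    if (any(y <= 0.2))
      stop("skeleton behind or too close to the camera plane")
    pts <- rbind(pts, cbind(
      u = camera$cx + camera$fx * x / y,
      v = camera$cy - camera$fy * (z - camera$cameraHeight) / y,
      pr = camera$fx * r / y,
      val = (y - r) * 1000))
  }
  if (is.null(pts)) return(depth)
  .Call(C_splat, depth, pts)
}

#' Render a depth sequence from skeleton streams
#'
#' Renders each body as a set of capsules (bone segments with radii) over a
#' constant background plane; each pixel reports the nearest surface
#' distance from the camera plane in millimeters. Deterministic under a
#' fixed seed.
#'
#' @param skeletons a \linkS4class{SkeletonSequence}, a list of them, or
#'   NULL for an empty scene.
#' @param camera a \code{\link{synthCamera}}.
#' @param noise a \code{\link{synthNoise}} (only \code{depthSigma} is used).
#' @param seed integer seed for the depth noise.
#' @param nFrames frame count, required when \code{skeletons} is NULL.
#' @param fps frame rate.
#' @return a \linkS4class{DepthSequence}.
#' @export
renderDepth <- function(skeletons, camera = synthCamera(),
                        noise = synthNoise(), seed = 0, nFrames = NULL,
                        fps = 8) {
  if (is(skeletons, "SkeletonSequence")) skeletons <- list(skeletons)
  if (is.null(skeletons) || !length(skeletons)) {
    if (is.null(nFrames)) stop("nFrames is required for an empty scene")
    T <- as.integer(nFrames)
  } else {
    T <- nFrames(skeletons[[1L]])
  }
  arr <- array(0L, dim = c(camera$height, camera$width, T))
  for (t in seq_len(T)) {
    d <- matrix(camera$backgroundDepth, camera$height, camera$width)
    for (sk in skeletons) {
      J <- sk@joints[t, , ]
      if (all(is.na(J))) next
      d <- pmin(d, renderOneFrame(J, camera))
    }
    arr[, , t] <- d
  }
  if (noise$depthSigma > 0) {
    withSeed(seed, {
      arr <- arr + array(rnorm(length(arr), 0, noise$depthSigma), dim = dim(arr))
    })
  }
  arr[] <- as.integer(pmax(0, round(arr)))
  DepthSequence(arr, fps = fps)
}

#' Build a session script
#'
#' @param labels character vector of action labels.
#' @param durations integer vector of per-entry durations (frames, >= 1).
#' @param noise a \code{\link{synthNoise}}.
#' @param camera a \code{\link{synthCamera}}.
#' @param seed integer seed.
#' @param fps frame rate.
#' @return list of class \code{sessionScript}.
#' @export
sessionScript <- function(labels, durations, noise = synthNoise(),
                          camera = synthCamera(), seed = 0, fps = 8) {
  stopifnot(length(labels) == length(durations), all(durations >= 1))
  structure(list(labels = as.character(labels),
                 durations = as.integer(durations), noise = noise,
                 camera = camera, seed = as.integer(seed), fps = fps),
            class = "sessionScript")
}

#' Generate a full synthetic session
#'
#' Concatenates per-entry skeleton clips (every clip starts and ends at the
#' rest pose, so handoffs are smooth), imputes tracking dropouts, renders
#' the depth video, and returns the three aligned modalities.
#'
#' @param script a \code{\link{sessionScript}}.
#' @return a \linkS4class{HomeSession}.
#' @examples
#' s <- makeSession(sessionScript(c("walking", "none_of_the_above"),
#'                                c(20, 15), synthNoise(0, 0, 0), seed = 1))
#' nFrames(s)
#' @export
makeSession <- function(script) {
  stopifnot(inherits(script, "sessionScript"))
  n <- length(script$labels)
  clips <- lapply(seq_len(n), function(i)
    makeSkeletonClip(script$labels[i], script$durations[i], script$noise,
                     seed = script$seed + 7919L * i, fps = script$fps))
  T <- sum(script$durations)
  S <- array(0, dim = c(T, 19L, 3L))
  off <- 0L
  for (cl in clips) {
    Ti <- nFrames(cl$skeleton)
    S[off + seq_len(Ti), , ] <- cl$skeleton@joints
    off <- off + Ti
  }
  skel <- SkeletonSequence(S, fps = script$fps)
  skel <- imputeJoints(skel)
  depth <- renderDepth(skel, script$camera, script$noise,
                       seed = script$seed, fps = script$fps)
  track <- FrameLabelTrack(rep(script$labels, script$durations))
  HomeSession(depth, skel, track)
}

#' Inject a second person into a session
#'
#' Adds a second tracked body (an idle bystander) to the skeleton stream
#' over a half-open frame span and composites it into the depth video.
#' Ground-truth labels are unchanged; the fixture exercises the
#' multi-person frame filter.
#'
#' @param session a \linkS4class{HomeSession}.
#' @param span half-open 0-based frame interval \code{c(start, end)}.
#' @param seed integer seed for the bystander's pose jitter.
#' @return a \linkS4class{HomeSession} with a second skeleton stream (NA
#'   joints outside the span).
#' @export
injectSecondPerson <- function(session, span, seed = 0) {
  T <- nFrames(session)
  s0 <- max(0L, as.integer(span[1L])); s1 <- min(T, as.integer(span[2L]))
  if (s1 <= s0) return(session)
  S <- array(NA_real_, dim = c(T, 19L, 3L))
  base <- restPose(x0 = -1.0, y0 = 3.2)
  withSeed(seed, {
    for (t in (s0 + 1L):s1)
      S[t, , ] <- base + matrix(rnorm(57, 0, 0.005), 19L, 3L)
  })
  extra <- SkeletonSequence(S, bodyId = 1L, fps = session@depth@fps)
  ## composite the bystander into the depth frames
  depth <- session@depth
  cam <- synthCamera(width = dim(depth@frames)[2L],
                     height = dim(depth@frames)[1L])
  for (t in (s0 + 1L):s1) {
    d <- renderOneFrame(S[t, , ], cam)
    depth@frames[, , t] <- pmin(depth@frames[, , t], as.integer(round(d)))
  }
  HomeSession(depth, c(session@skeletons, list(extra)), session@track)
}

#' Which frames of a skeleton stream have the body present
#'
#' @param skeleton a \linkS4class{SkeletonSequence} (absent frames all-NA).
#' @return logical vector of length T.
#' @export
bodyPresent <- function(skeleton) {
  apply(is.finite(skeleton@joints), 1L, any)
}

#' Generate a batch of single-action sessions
#'
#' Each session is one action instance flanked by background: background
#' pad, one of the five action classes, background pad. Durations and the
#' class cycle are drawn deterministically from the seed. This is the
#' dataset layout used by the desk-scale end-to-end experiments.
#'
#' @param n number of sessions.
#' @param seed integer master seed.
#' @param noise a \code{\link{synthNoise}}.
#' @param camera a \code{\link{synthCamera}}.
#' @param fps frame rate.
#' @return list of \linkS4class{HomeSession}.
#' @export
simulateSessions <- function(n, seed = 0, noise = synthNoise(),
                             camera = synthCamera(), fps = 8) {
  classes <- setdiff(actionTaxonomy(), backgroundLabel())
  plan <- withSeed(seed, {
    data.frame(label = classes[(seq_len(n) - 1L) %% length(classes) + 1L],
               pre = sample(10:16, n, replace = TRUE),
               act = sample(16:28, n, replace = TRUE),
               post = sample(10:16, n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    makeSession(sessionScript(
      c(backgroundLabel(), plan$label[i], backgroundLabel()),
      c(plan$pre[i], plan$act[i], plan$post[i]),
      noise = noise, camera = camera, seed = seed + 104729L * i, fps = fps))
  })
}
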