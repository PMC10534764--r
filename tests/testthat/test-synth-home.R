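test_that("reaching trajectories follow the raise-hold-lower convention", {
  clip <- makeSkeletonClip("reaching_overhead", 30, quietNoise(), 0)
  wz <- joints3d(clip$skeleton)[, "wrist_r", "z"]
  hz <- joints3d(clip$skeleton)[, "head", "z"]
  mid <- 10:20
  expect_true(any(wz[mid] > hz[mid]))          # above the head mid-clip
  expect_lt(wz[1], hz[1])                       # starts below
  expect_equal(wz[30], wz[1], tolerance = 1e-9) # returns to rest
  ## unimodal: increases then decreases
  peak <- which.max(wz)
  expect_true(all(diff(wz[1:peak]) >= -1e-9))
  expect_true(all(diff(wz[peak:30]) <= 1e-9))
})

test_that("every reaching class starts and ends at the rest pose", {
  for (lab in c("reaching_overhead", "reaching_forward",
                "reaching_below_waist")) {
    clip <- makeSkeletonClip(lab, 24, quietNoise(), 1)
    S <- joints3d(clip$skeleton)
    expect_equal(S[1, , ], S[24, , ], tolerance = 1e-9)
  }
})

test_that("walking translates the root and the idle class stays near rest", {
  walk <- makeSkeletonClip("walking", 40, quietNoise(), 0)
  rootX <- joints3d(walk$skeleton)[, "mid_hip", "x"]
  expect_gt(max(abs(diff(rootX))), 0.01)       # the body really moves
  expect_gt(diff(range(rootX)), 1)             # over a meter of travel

  idle <- makeSkeletonClip("none_of_the_above", 20, quietNoise(), 0)
  disp <- apply(joints3d(idle$skeleton), c(2, 3), function(v) diff(range(v)))
  expect_lt(max(disp), 0.02)                   # below idle threshold

  manip <- makeSkeletonClip("hand_manipulation", 20, quietNoise(), 0)
  wr <- joints3d(manip$skeleton)[, "wrist_r", ]
  expect_lt(max(apply(wr, 2, function(v) diff(range(v)))), 0.3)
})

test_that("the generator is a pure function of label, size and seed", {
  a <- makeSkeletonClip("walking", 15, synthNoise(), 7)
  b <- makeSkeletonClip("walking", 15, synthNoise(), 7)
  expect_identical(a$skeleton@joints, b$skeleton@joints)
  c <- makeSkeletonClip("walking", 15, synthNoise(), 8)
  expect_false(identical(a$skeleton@joints, c$skeleton@joints))
  expect_error(makeSkeletonClip("jumping", 15), "unknown action")
})

test_that("the renderer draws the body in front of a constant background", {
  cam <- synthCamera()
  empty <- renderDepth(NULL, cam, quietNoise(), 0, nFrames = 3)
  expect_true(all(depthFrames(empty) == cam$backgroundDepth))

  clip <- makeSkeletonClip("none_of_the_above", 5, quietNoise(), 0)
  d <- renderDepth(clip$skeleton, cam, quietNoise(), 0)
  fr <- depthFrames(d)
  expect_true(any(fr < cam$backgroundDepth))   # silhouette closer
  expect_true(all(fr >= 0))
  expect_lt(min(fr), 3000)                      # person at about 2.5 m

  d2 <- renderDepth(clip$skeleton, cam, quietNoise(), 0)
  expect_identical(depthFrames(d), depthFrames(d2))  # deterministic

  behind <- clip$skeleton
  behind@joints[, , 2] <- -1                    # behind the camera plane
  expect_error(renderDepth(behind, cam, quietNoise(), 0), "behind")
})

test_that("sessions concatenate clips with aligned ground truth", {
  s <- makeSession(sessionScript(
    c("walking", "none_of_the_above", "reaching_forward"),
    c(40, 60, 30), noise = quietNoise(), seed = 5))
  expect_equal(nFrames(s), 130L)
  expect_equal(nFrames(sessionDepth(s)), 130L)
  expect_equal(nFrames(sessionSkeletons(s)[[1]]), 130L)
  runs <- segmentTable(segmentsFromTrack(sessionTrack(s)))
  expect_equal(nrow(runs), 3L)
  expect_equal(runs$label,
               c("walking", "none_of_the_above", "reaching_forward"))

  ## different seeds: same labels, different depth noise
  s2 <- makeSession(sessionScript(
    c("walking", "none_of_the_above", "reaching_forward"),
    c(40, 60, 30), noise = synthNoise(), seed = 5))
  s3 <- makeSession(sessionScript(
    c("walking", "none_of_the_above", "reaching_forward"),
    c(40, 60, 30), noise = synthNoise(), seed = 6))
  expect_identical(frameLabels(s2), frameLabels(s3))
  expect_false(identical(depthFrames(sessionDepth(s2)),
                         depthFrames(sessionDepth(s3))))
})

test_that("a second person appears exactly within the requested span", {
  s <- fixtureSession(seed = 3, durations = c(15, 20, 15))
  s2 <- injectSecondPerson(s, c(10, 20), seed = 1)
  expect_length(sessionSkeletons(s2), 2L)
  pres <- bodyPresent(sessionSkeletons(s2)[[2]])
  expect_identical(which(pres), 11:20)
  expect_identical(frameLabels(s2), frameLabels(s))

  expect_identical(nFrames(injectSecondPerson(s, c(10, 10))), nFrames(s))
  expect_length(sessionSkeletons(injectSecondPerson(s, c(10, 10))), 1L)
})

test_that("dropout produces missing joints that imputation repairs", {
  clip <- makeSkeletonClip("walking", 40, synthNoise(0, 0, 0.2), 1)
  expect_true(anyNA(clip$skeleton@joints))
  fixed <- imputeJoints(clip$skeleton)
  expect_false(anyNA(fixed@joints))
})
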