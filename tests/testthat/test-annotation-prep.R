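bg <- "none_of_the_above"

test_that("short action runs are removed and long background runs truncated", {
  ## non-background runs of lengths 3, 4, 5, 10 separated by background
  tr <- bgTrack(c(none_of_the_above = 10, walking = 3, none_of_the_above = 10,
                  reaching_forward = 4, none_of_the_above = 10,
                  hand_manipulation = 5, none_of_the_above = 10,
                  walking = 10, none_of_the_above = 10))
  out <- cleanTrack(tr)
  runs <- segmentTable(segmentsFromTrack(out))
  act <- runs[runs$label != bg, ]
  expect_equal(sort(act$end - act$start), c(5, 10))  # 3 and 4 removed
  expect_setequal(act$label, c("hand_manipulation", "walking"))

  ## 300-frame background run shortened to its first 50 frames
  tr2 <- bgTrack(c(walking = 10, none_of_the_above = 300, walking = 10))
  out2 <- cleanTrack(tr2)
  runs2 <- segmentTable(segmentsFromTrack(out2))
  expect_equal(runs2$end - runs2$start, c(10, 50, 10))
  expect_equal(nFrames(out2), 70L)

  ## boundary: exactly 150 frames is NOT "greater than 150"
  tr3 <- bgTrack(c(walking = 10, none_of_the_above = 150, walking = 10))
  expect_equal(nFrames(cleanTrack(tr3)), 170L)
  ## 151 frames is
  tr4 <- bgTrack(c(walking = 10, none_of_the_above = 151, walking = 10))
  expect_equal(nFrames(cleanTrack(tr4)), 70L)
})

test_that("cleanTrack is idempotent and reports a frame index map", {
  tr <- bgTrack(c(none_of_the_above = 200, walking = 3,
                  none_of_the_above = 20, reaching_overhead = 12))
  once <- cleanTrack(tr)
  twice <- cleanTrack(once)
  expect_identical(frameLabels(once), frameLabels(twice))

  withIdx <- cleanTrack(tr, returnIndex = TRUE)
  expect_identical(frameLabels(withIdx$track), frameLabels(once))
  expect_identical(frameLabels(tr)[withIdx$keep] == bg |
                     frameLabels(withIdx$track) == frameLabels(tr)[withIdx$keep],
                   rep(TRUE, length(withIdx$keep)))
})

test_that("multi-person frames are filtered from all modalities", {
  s <- fixtureSession(seed = 4, durations = c(15, 20, 15))
  s2 <- injectSecondPerson(s, c(10, 20), seed = 1)
  flt <- filterMultiperson(s2)
  expect_equal(nFrames(flt$session), 40L)       # 50 - 10 removed
  expect_identical(flt$keep, c(1:10, 21:50))
  expect_equal(nFrames(sessionDepth(flt$session)), 40L)
  expect_identical(frameLabels(flt$session), frameLabels(s)[flt$keep])
  ## survivors keep their original order
  expect_true(all(diff(flt$keep) > 0))

  ## single-person input is untouched
  flt1 <- filterMultiperson(s)
  expect_equal(nFrames(flt1$session), 50L)
  expect_identical(flt1$keep, 1:50)

  ## every frame two-person -> empty output
  s3 <- injectSecondPerson(s, c(0, 50), seed = 2)
  flt3 <- filterMultiperson(s3)
  expect_equal(nFrames(flt3$session), 0L)
})

test_that("tracks and segments convert back and forth as exact inverses", {
  tr <- FrameLabelTrack(c("walking", "walking", bg, bg, bg,
                          "reaching_forward"))
  segs <- segmentsFromTrack(tr)
  df <- segmentTable(segs)
  expect_equal(df$start, c(0, 2, 5))
  expect_equal(df$end, c(2, 5, 6))
  expect_equal(df$label, c("walking", bg, "reaching_forward"))

  expect_identical(frameLabels(trackFromSegments(segs, 6)),
                   frameLabels(tr))

  const <- FrameLabelTrack(rep("walking", 9))
  expect_equal(length(segmentsFromTrack(const)), 1L)
})

test_that("segmentsFromTrack tiles the frame axis without gaps or overlaps", {
  set.seed(5)
  for (rep in 1:20) {
    labs <- sample(actionTaxonomy(), 30, replace = TRUE)
    segs <- segmentTable(segmentsFromTrack(FrameLabelTrack(labs)))
    expect_equal(segs$start[1], 0)
    expect_equal(segs$end[nrow(segs)], 30)
    if (nrow(segs) > 1)
      expect_equal(segs$start[-1], segs$end[-nrow(segs)])
    expect_identical(frameLabels(trackFromSegments(
      segmentsFromTrack(FrameLabelTrack(labs)), 30)), labs)
  }
})

test_that("augmentation preserves labels, mirrors involutively, resamples", {
  s <- fixtureSession(seed = 9, durations = c(8, 30, 8))
  clip <- extractClips(s)[[2]]
  expect_equal(clip$label, "walking")

  m1 <- augmentClip(clip, seed = 1, ops = "mirror")
  m2 <- augmentClip(m1, seed = 1, ops = "mirror")
  expect_equal(m2$depth@frames, clip$depth@frames)
  expect_equal(m2$skeleton@joints, clip$skeleton@joints, tolerance = 1e-12)
  expect_true(m1$augmented)

  r <- augmentClip(clip, seed = 2, ops = "resample")
  Tnew <- dim(r$depth@frames)[3]
  expect_true(Tnew >= 24 && Tnew <= 36)   # within +/-20% of 30
  expect_equal(r$label, clip$label)

  n <- augmentClip(clip, seed = 3, ops = "noise")
  expect_equal(n$label, clip$label)
  expect_false(identical(n$depth@frames, clip$depth@frames))

  a <- augmentClip(clip, seed = 4)
  b <- augmentClip(clip, seed = 4)
  expect_identical(a$depth@frames, b$depth@frames)  # seeded
})

test_that("balancing augments rare classes and down-samples background", {
  mk <- function(lab) actionClip(
    depth = DepthSequence(array(1000L, dim = c(8, 8, 10))),
    skeleton = makeSkeletonClip(lab, 10, quietNoise(), 1)$skeleton,
    label = lab)
  clips <- c(replicate(20, mk("walking"), simplify = FALSE),
             replicate(4, mk("reaching_forward"), simplify = FALSE),
             replicate(60, mk(bg), simplify = FALSE))
  out <- balanceDataset(clips, seed = 1)
  labs <- vapply(out, `[[`, "", "label")
  counts <- table(factor(labs, levels = actionTaxonomy()))
  expect_gte(counts[["reaching_forward"]], 10)     # >= half of max (20)
  expect_lte(counts[[bg]], 20)                     # capped at max action
  expect_equal(counts[["walking"]], 20)
  aug <- vapply(out, `[[`, TRUE, "augmented")
  expect_true(any(aug))
  expect_true(all(vapply(out[aug], `[[`, "", "label") != bg))

  ## already balanced input passes through unchanged
  bal <- c(replicate(10, mk("walking"), simplify = FALSE),
           replicate(10, mk("reaching_forward"), simplify = FALSE))
  expect_length(balanceDataset(bal, seed = 1), 20L)
})
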