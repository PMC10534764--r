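bg <- "none_of_the_above"

test_that("vote fusion matches the two-agree-else-background rule", {
  expect_equal(frameLabels(fuseFrameVotes("walking", "walking", bg)),
               "walking")
  expect_equal(frameLabels(fuseFrameVotes("walking", "reaching_forward",
                                          "hand_manipulation")), bg)
  for (x in actionTaxonomy())
    expect_equal(frameLabels(fuseFrameVotes(x, x, x)), x)
  expect_error(fuseFrameVotes(c("walking", bg), "walking", "walking"),
               "equal length")
})

test_that("vote fusion matches exhaustive enumeration over label triples", {
  labels <- actionTaxonomy()
  oracle <- function(a, b, c) {
    votes <- table(c(a, b, c))
    top <- names(votes)[votes >= 2]
    if (length(top)) top else bg
  }
  for (a in labels) for (b in labels) for (c in labels) {
    expect_equal(frameLabels(fuseFrameVotes(a, b, c)), oracle(a, b, c),
                 info = paste(a, b, c))
  }
})

test_that("fusion is symmetric under permutation of the three networks", {
  set.seed(10)
  a <- sample(actionTaxonomy(), 60, TRUE)
  b <- sample(actionTaxonomy(), 60, TRUE)
  c <- sample(actionTaxonomy(), 60, TRUE)
  f0 <- frameLabels(fuseFrameVotes(a, b, c))
  expect_identical(frameLabels(fuseFrameVotes(b, c, a)), f0)
  expect_identical(frameLabels(fuseFrameVotes(c, a, b)), f0)
  expect_identical(frameLabels(fuseFrameVotes(b, a, c)), f0)
})

test_that("per-frame precision counts matching frames", {
  t1 <- rep(c("walking", bg), c(4, 6))
  expect_equal(perFramePrecision(t1, t1), 1)
  t2 <- rep(c(bg, "walking"), c(4, 6))
  expect_equal(perFramePrecision(t1, t2), 0)
  t3 <- t1; t3[1:2] <- bg
  expect_equal(perFramePrecision(t3, t1), 0.8)
  set.seed(1)
  anything <- sample(actionTaxonomy(), 30, TRUE)
  expect_equal(perFramePrecision(anything, anything), 1)
})

test_that("per-action precision uses one-to-one IoU matching", {
  gt <- ActionSegments(c(0, 30), c(20, 50), c("walking", "reaching_forward"))
  expect_equal(perActionPrecision(gt, gt), 1)

  ## one of two predictions matches
  pred <- ActionSegments(c(0, 60), c(20, 80),
                         c("walking", "reaching_forward"), c(0.9, 0.8))
  expect_equal(perActionPrecision(pred, gt), 0.5)

  ## right label, IoU 0.4 < 0.5: unmatched
  p2 <- ActionSegments(0, 50, "walking", 1)   # IoU vs (0,20) = 0.4
  expect_equal(perActionPrecision(p2, gt), 0)
  expect_equal(perActionPrecision(p2, gt, iouThr = 0.3), 1)

  ## two predictions cannot claim the same ground truth
  dup <- ActionSegments(c(0, 0), c(20, 20), c("walking", "walking"),
                        c(0.9, 0.8))
  expect_equal(perActionPrecision(dup, gt), 0.5)

  ## no predictions: defined as 0 with a warning
  expect_warning(v <- perActionPrecision(ActionSegments(), gt), "no predicted")
  expect_equal(as.numeric(v), 0)
})

test_that("per-action precision is monotone non-increasing in the threshold", {
  set.seed(13)
  gt <- ActionSegments(c(0, 40, 90), c(25, 70, 120),
                       c("walking", "reaching_forward", "walking"))
  pred <- ActionSegments(c(2, 45, 95, 150), c(22, 80, 115, 170),
                         c("walking", "reaching_forward", "walking",
                           "hand_manipulation"), c(0.9, 0.8, 0.7, 0.6))
  thrs <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(thrs, function(th) perActionPrecision(pred, gt, th), 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("confusion matrix counts, normalizes by row, conserves frames", {
  gt <- rep(c("walking", bg), c(6, 4))
  cm <- confusionMatrix(gt, gt)
  expect_equal(sum(cm$counts), 10)
  expect_equal(unname(diag(cm$normalized)[c(1, 6)]), c(1, 1))

  allBg <- rep(bg, 10)
  cm2 <- confusionMatrix(allBg, gt)
  expect_equal(sum(cm2$counts[, bg]), 10)      # all mass in background col
  expect_equal(unname(cm2$normalized["walking", bg]), 1)

  ## absent classes keep all-zero rows after normalization
  expect_true(all(cm2$normalized["reaching_forward", ] == 0))
})

test_that("metrics report aggregates frame and action views", {
  gtTrack <- FrameLabelTrack(rep(c(bg, "walking", bg), c(10, 20, 10)))
  rep1 <- metricsReport(gtTrack, gtTrack)
  expect_equal(rep1$perFramePrecision, 1)
  expect_equal(rep1$perFramePrecisionNoBg, 1)
  expect_equal(rep1$perActionPrecision, 1)
  expect_output(print(rep1), "per-frame precision")
})
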