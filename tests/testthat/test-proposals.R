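test_that("anchors are uniformly placed, one per scale and position", {
  defaultScales <- c(2, 4, 5, 6, 8, 9, 10, 12, 14, 16)
  a <- generateAnchors(4, defaultScales, 8)
  expect_equal(nrow(a), 40L)

  a2 <- generateAnchors(2, 2, 8)
  expect_equal(a2$center, c(4, 12))
  expect_equal(a2$length, c(2, 2))

  a3 <- generateAnchors(3, c(50, 100, 200, 400), 4)
  expect_equal(nrow(a3), 12L)
  expect_setequal(unique(a3$length), c(50, 100, 200, 400))
})

test_that("offset transforms match the closed form and invert exactly", {
  e <- encodeOffsets(10, 8, 8, 4)
  expect_equal(e$tx, 0.5)
  expect_equal(e$tw, log(2))

  e0 <- encodeOffsets(7, 3, 7, 3)
  expect_equal(unlist(e0), c(tx = 0, tw = 0))

  expect_error(encodeOffsets(5, -1, 5, 2), "positive")
  expect_error(decodeOffsets(0, 0, 5, 0), "positive")

  set.seed(8)
  n <- 1e4
  xa <- runif(n, 0, 500); wa <- runif(n, 1, 100)
  x <- runif(n, 0, 500); w <- runif(n, 0.5, 200)
  enc <- encodeOffsets(x, w, xa, wa)
  dec <- decodeOffsets(enc$tx, enc$tw, xa, wa)
  expect_lt(max(abs(dec$center - x)), 1e-9)
  expect_lt(max(abs(dec$length - w)), 1e-9)
})

test_that("temporal IoU behaves on half-open intervals", {
  expect_equal(temporalIoU(3, 9, 3, 9), 1)
  expect_equal(temporalIoU(0, 5, 5, 10), 0)
  expect_equal(temporalIoU(0, 10, 5, 15), 5 / 15)
  expect_equal(temporalIoU(0, 10, 5, 15), temporalIoU(5, 15, 0, 10))
  set.seed(2)
  s <- runif(50); e <- s + runif(50); s2 <- runif(50); e2 <- s2 + runif(50)
  iou <- temporalIoU(s, e, s2, e2)
  expect_true(all(iou >= 0 & iou <= 1))
  expect_equal(iou, temporalIoU(s2, e2, s, e))
})

test_that("anchor target assignment follows the pos/neg/ignore rule", {
  anchors <- data.frame(center = c(21, 100, 14), length = c(18, 10, 10),
                        position = 0:2, scale = 1)
  gt <- ActionSegments(12, 30, "walking")
  tgt <- assignAnchorTargets(anchors, gt, posThr = 0.7, negThr = 0.3)
  expect_equal(tgt$label[1], 1)                 # exact-ish anchor positive
  expect_equal(tgt$label[2], 0)                 # disjoint anchor negative
  expect_equal(tgt$gtLabel[1], "walking")
  expect_equal(tgt$tx[1], (21 - 21) / 18)
  expect_equal(tgt$tw[1], log(18 / 18))

  ## IoU 0.5 anchor between the thresholds is ignored (NA)
  anchors2 <- data.frame(center = c(10), length = c(10), position = 0,
                         scale = 1)
  gt2 <- ActionSegments(5, 25, "walking")       # IoU = 10/20 = 0.5
  ## force-matching would make the single best anchor positive; add a
  ## better anchor so the middling one keeps its in-between status
  anchors2 <- rbind(anchors2,
                    data.frame(center = 15, length = 20, position = 1,
                               scale = 2))
  tgt2 <- assignAnchorTargets(anchors2, gt2, posThr = 0.7, negThr = 0.3)
  expect_true(is.na(tgt2$label[1]))
  expect_equal(tgt2$label[2], 1)

  ## anchors facing no ground truth are all negative
  tgt3 <- assignAnchorTargets(anchors, ActionSegments())
  expect_true(all(tgt3$label == 0))
})

test_that("every ground truth gets at least one positive anchor", {
  anchors <- generateAnchors(6, c(2, 4, 5, 6, 8, 9, 10, 12, 14, 16), 8)
  gt <- ActionSegments(16, 32, "walking")       # between anchor centers
  tgt <- assignAnchorTargets(anchors, gt)
  expect_gte(sum(tgt$label == 1, na.rm = TRUE), 1)
})

test_that("greedy NMS keeps the expected survivors deterministically", {
  two <- ActionSegments(c(0, 0), c(10, 10), c("walking", "walking"),
                        c(0.9, 0.8))
  kept <- segmentTable(nmsSegments(two, 0.5))
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)

  disjoint <- ActionSegments(c(0, 20, 40), c(10, 30, 50), rep("walking", 3),
                             c(0.3, 0.2, 0.1))
  expect_equal(length(nmsSegments(disjoint, 0.5)), 3L)

  ## chain: IoU(1,2) = 1/3 >= 0.3 suppresses 2; IoU(1,3) = 0 keeps 3
  chain <- ActionSegments(c(0, 5, 12), c(10, 15, 22), rep("walking", 3),
                          c(0.9, 0.8, 0.7))
  kept <- segmentTable(nmsSegments(chain, 0.3))
  expect_equal(kept$start, c(0, 12))
  expect_equal(kept$score, c(0.9, 0.7))         # scores pass through

  ## input order must not matter for distinct scores
  perm <- ActionSegments(c(12, 0, 5), c(22, 10, 15), rep("walking", 3),
                         c(0.7, 0.9, 0.8))
  expect_identical(segmentTable(nmsSegments(perm, 0.3)),
                   segmentTable(nmsSegments(chain, 0.3)))
})

test_that("the joint loss is zero at perfection and gates regression", {
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(jointLoss(p, c(1, 2), c(0, 0), matrix(0, 2, 2),
                         matrix(0, 2, 2)), 0)
  expect_equal(jointLoss(p, c(1, 2), c(1, 1), matrix(0, 2, 2),
                         matrix(0, 2, 2)), 0)

  ## regression ignored wherever the anchor label is 0
  wild <- matrix(c(100, -50, 3, 7), 2, 2)
  expect_equal(jointLoss(p, c(1, 2), c(0, 0), wild, matrix(0, 2, 2)), 0)

  ## single positive with offset error (0.5, 0): smooth L1 = 0.5 * 0.25
  l <- jointLoss(matrix(c(1, 0), 1), 1, 1, matrix(c(0.5, 0), 1),
                 matrix(0, 1, 2), lambda = 1, nReg = 1)
  expect_equal(l, 0.125)

  ## the kink: |u| >= 1 switches to |u| - 0.5
  l2 <- jointLoss(matrix(c(1, 0), 1), 1, 1, matrix(c(2, 0), 1),
                  matrix(0, 1, 2), lambda = 1, nReg = 1)
  expect_equal(l2, 1.5)

  ## non-negative on random inputs
  set.seed(4)
  for (i in 1:20) {
    z <- matrix(runif(12), 4, 3); z <- z / rowSums(z)
    expect_gte(jointLoss(z, sample(3, 4, TRUE), sample(0:1, 4, TRUE),
                         matrix(rnorm(8), 4, 2), matrix(rnorm(8), 4, 2)), 0)
  }
})

test_that("temporal RoI pooling is a per-bin max with fixed output length", {
  expect_equal(roiPoolTemporal(c(1, 5, 3, 9), c(0, 4), 2), c(5, 9))
  expect_equal(roiPoolTemporal(c(1, 5, 3, 9), c(0, 4), 4), c(1, 5, 3, 9))
  expect_equal(roiPoolTemporal(rep(7, 10), c(2, 9), 3), rep(7, 3))
  expect_error(roiPoolTemporal(1:4, c(2, 2), 2), "non-empty")

  ## brute-force bin-max oracle on random maps
  set.seed(6)
  for (case in 1:25) {
    Tn <- sample(5:20, 1); C <- sample(1:4, 1); out <- sample(1:5, 1)
    fm <- matrix(rnorm(C * Tn), C, Tn)
    s <- runif(1, 0, Tn - 1.5); e <- runif(1, s + 1, Tn)
    got <- roiPoolTemporal(fm, c(s, e), out)
    if (is.null(dim(got))) got <- matrix(got, 1)
    for (i in seq_len(out)) {
      b0 <- s + (i - 1) * (e - s) / out; b1 <- s + i * (e - s) / out
      p0 <- max(floor(s), floor(b0)); p1 <- min(ceiling(e) - 1, ceiling(b1) - 1)
      if (p1 < p0) p1 <- p0
      expect_equal(got[, i],
                   apply(fm[, (p0:p1) + 1, drop = FALSE], 1, max))
    }
  }
})
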