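test_that("skeletal motion is the zero-padded first difference", {
  S <- array(0, dim = c(3, 19, 3))
  S[, 1, 1] <- c(0, 1, 3)
  M <- skeletonMotion(S)
  expect_equal(M[, 1, 1], c(1, 2, 0))
  expect_equal(dim(M), dim(S))

  static <- array(2, dim = c(5, 19, 3))
  expect_true(all(skeletonMotion(static) == 0))

  v <- array(0, dim = c(6, 19, 3))
  for (t in 1:6) v[t, , ] <- t * 0.1
  Mv <- skeletonMotion(v)
  expect_true(all(abs(Mv[1:5, , ] - 0.1) < 1e-12))
  expect_true(all(Mv[6, , ] == 0))

  expect_error(skeletonMotion(array(0, dim = c(1, 19, 3))), "2 frames")
})

test_that("motion equals a naive per-joint loop and ignores translation", {
  set.seed(3)
  S <- array(rnorm(8 * 19 * 3), dim = c(8, 19, 3))
  M <- skeletonMotion(S)
  for (j in sample(19, 4)) for (d in 1:3) {
    naive <- c(diff(S[, j, d]), 0)
    expect_equal(M[, j, d], naive)
  }
  ## constant offset on every joint leaves motion unchanged
  S2 <- S + 0.77
  expect_equal(skeletonMotion(S2), M)
})

test_that("the transform stage swaps the joint and coordinate axes", {
  cfg <- rhcnConfig(pointWidth = 2, coocWidth = 3, mergeWidth = 4,
                    fcWidth = 6)
  ns <- asNamespace("DepthTAL")
  layers <- ns$rhcnStreamLayers(cfg)
  kinds <- vapply(layers, `[[`, "", "kind")
  expect_true("permNC" %in% kinds)
  ## point-level convs keep kernel extent 1 along the joint axis
  firstConv <- layers[[which(kinds == "conv3")[1]]]
  expect_equal(firstConv$k[1:2], c(1L, 1L))
  ## the co-occurrence conv after the transform spans joints as channels
  post <- which(kinds == "permNC")
  coocConv <- layers[[post + 1L]]
  expect_equal(dim(coocConv$W)[4], 19L)
})

test_that("a tiny model runs forward on a T=100 sequence", {
  cfg <- rhcnConfig(pointWidth = 2, coocWidth = 3, mergeWidth = 4,
                    fcWidth = 6)
  m <- buildRhcn(cfg, seed = 0)
  clip <- makeSkeletonClip("walking", 100, quietNoise(), 1)
  det <- detectRhcn(m, clip$skeleton)
  expect_equal(nFrames(det$track), 100L)
  expect_true(all(is.finite(segmentTable(det$segments)$score)))
})

test_that("label restriction drops non-walking detections", {
  cfg <- rhcnConfig(pointWidth = 2, coocWidth = 3, mergeWidth = 4,
                    fcWidth = 6)
  m <- buildRhcn(cfg, seed = 2)
  clip <- makeSkeletonClip("reaching_forward", 60, quietNoise(), 3)
  detAll <- detectRhcn(m, clip$skeleton, restrictLabels = "all")
  detW <- detectRhcn(m, clip$skeleton)           # default: walking only
  expect_true(all(segmentTable(detW$segments)$label == "walking"))
  expect_true(all(frameLabels(detW$track) %in%
                    c("walking", backgroundLabel())))
  expect_gte(length(detAll$segments), length(detW$segments))

  empty <- SkeletonSequence(array(0, dim = c(1, 19, 3)))
  detE <- detectRhcn(m, empty)
  expect_length(detE$segments, 0L)
})

test_that("paper profile leaves RHCN weights effectively frozen", {
  cfg <- rhcnConfig(pointWidth = 2, coocWidth = 3, mergeWidth = 4,
                    fcWidth = 6)
  m <- buildRhcn(cfg, seed = 0)
  sessions <- lapply(1:2, function(i)
    makeSession(sessionScript(c("none_of_the_above", "walking"),
                              c(8, 16), noise = quietNoise(), seed = i)))
  hy <- hyperProfile("paper")$rhcn
  expect_equal(hy$lr, 1e-14)
  hy$epochs <- 1
  m2 <- trainRhcn(m, sessions, hy, seed = 1)
  expect_lt(max(abs(m2$streamS[[1]]$W - m$streamS[[1]]$W)), 1e-8)
  expect_true(all(is.finite(m2$history)))        # loss finite on first batch
})

test_that("desk training detects long walking bouts in skeleton data", {
  ## walking bouts of 40-60 frames within T ~ 100 sessions, so the
  ## [50, 100, 200, 400] anchor scales can reach IoU 0.5
  sessions <- lapply(1:20, function(i) {
    lab <- c("walking", "none_of_the_above")[(i %% 2) + 1]
    makeSession(sessionScript(
      c("none_of_the_above", lab, "none_of_the_above"),
      c(20, 50, 20), noise = quietNoise(), seed = i))
  })
  m <- buildRhcn(rhcnConfig(), seed = 0)
  hy <- hyperProfile("desk")$rhcn
  hy$epochs <- 25
  m <- trainRhcn(m, sessions, hy, seed = 1)
  hits <- 0; nW <- 0
  for (i in 21:26) {
    lab <- c("walking", "none_of_the_above")[(i %% 2) + 1]
    s <- makeSession(sessionScript(
      c("none_of_the_above", lab, "none_of_the_above"),
      c(20, 50, 20), noise = quietNoise(), seed = i))
    det <- detectRhcn(m, sessionSkeletons(s)[[1]])
    df <- segmentTable(det$segments)
    if (lab == "walking") {
      nW <- nW + 1
      if (nrow(df) && max(temporalIoU(df$start, df$end, 20, 70)) >= 0.5)
        hits <- hits + 1
    }
  }
  expect_gt(hits / nW, 0.5)
})
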