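test_that("depth PNG round trip is bit-exact and range-checked", {
  p <- withr::local_tempfile(fileext = ".png")

  f0 <- matrix(0L, 4, 4)
  writeDepthPNG(f0, p)
  expect_identical(readDepthPNG(p), f0)

  f1 <- matrix(0L, 4, 4); f1[2, 3] <- 2500L
  writeDepthPNG(f1, p)
  expect_identical(readDepthPNG(p), f1)

  set.seed(7)
  f2 <- matrix(sample.int(65536, 15 * 11) - 1L, 15, 11)
  writeDepthPNG(f2, p)
  expect_identical(readDepthPNG(p), f2)

  expect_error(writeDepthPNG(matrix(70000, 2, 2), p), "16 bits")
})

test_that("non-PNG input is rejected as a format error", {
  p <- withr::local_tempfile(fileext = ".png")
  writeLines("definitely not a png", p)
  expect_error(readDepthPNG(p), "not a PNG")
})

test_that("cache blocks hold at most 30 frames and round trip losslessly", {
  frames30 <- lapply(1:30, function(i) matrix(as.integer(i * 11), 3, 5))
  b <- packCache(frames30)
  expect_identical(unpackCache(b), frames30)
  ## header frame count sits after the 8-byte magic, little-endian u32
  expect_identical(as.integer(b[9]), 30L)

  one <- list(matrix(7L, 2, 2))
  expect_identical(unpackCache(packCache(one)), one)

  frames31 <- c(frames30, list(matrix(0L, 3, 5)))
  expect_error(packCache(frames31), "capacity")
})

test_that("cache checksum detects payload corruption", {
  b <- packCache(lapply(1:5, function(i) matrix(as.integer(i), 4, 4)))
  ## flip one bit in the tampered copy's payload region
  i <- 30L
  b[i] <- as.raw(bitwXor(as.integer(b[i]), 1L))
  expect_error(unpackCache(b), "checksum")
})

test_that("cache round trip holds for randomized frame stacks", {
  set.seed(42)
  for (case in 1:100) {
    n <- sample.int(30, 1)
    h <- sample(2:6, 1); w <- sample(2:6, 1)
    frames <- lapply(seq_len(n), function(i)
      matrix(sample.int(65536, h * w, replace = TRUE) - 1L, h, w))
    expect_identical(unpackCache(packCache(frames)), frames)
  }
})

test_that("single-byte payload corruptions are always detected", {
  frames <- lapply(1:3, function(i) matrix(as.integer(i * 100), 3, 3))
  b <- packCache(frames)
  plen <- length(b) - 28L
  set.seed(9)
  for (off in sample(seq_len(plen), min(20L, plen))) {
    bb <- b
    bb[24L + off] <- as.raw(bitwXor(as.integer(bb[24L + off]), 255L))
    expect_error(unpackCache(bb), "checksum|truncated")
  }
})

test_that("skeleton streams group by body and round trip", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  clip <- makeSkeletonClip("walking", 10, quietNoise(), 1)
  writeSkeletonStream(clip$skeleton, p)
  r <- readSkeletonStream(p)
  expect_length(r, 1L)
  expect_identical(r[[1]]@joints, clip$skeleton@joints)
  expect_identical(r[[1]]@timestamps, clip$skeleton@timestamps)

  ## two interleaved bodies, 5 frames each
  s2 <- makeSkeletonClip("none_of_the_above", 5, quietNoise(), 2)$skeleton
  s2@bodyId <- 1L
  s1 <- makeSkeletonClip("walking", 5, quietNoise(), 3)$skeleton
  writeSkeletonStream(list(s1, s2), p)
  r2 <- readSkeletonStream(p)
  expect_length(r2, 2L)
  expect_identical(vapply(r2, nFrames, 0L), c(5L, 5L))
  expect_identical(vapply(r2, bodyId, 0L), c(0L, 1L))
})

test_that("empty skeleton stream file reads as empty result", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), p)
  expect_identical(readSkeletonStream(p), list())
})

test_that("a record with the wrong joint count is a schema error", {
  p <- withr::local_tempfile(fileext = ".jsonl")
  rec <- list(ts = 0, body = 0L, j3 = matrix(0, 18, 3),
              j2 = matrix(0, 18, 2), floor = c(0, 0, 1, 0))
  writeLines(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE)), p)
  expect_error(readSkeletonStream(p), "19-joint")
})

test_that("segment files round trip sorted by start, overlaps preserved", {
  p <- withr::local_tempfile(fileext = ".tsv")
  segs <- ActionSegments(c(5, 0, 3), c(15, 10, 12),
                         c("walking", "walking", "reaching_forward"),
                         c(0.5, 0.9, 0.7))
  writeSegments(segs, p)
  r <- readSegments(p)
  df <- segmentTable(r)
  expect_equal(df$start, c(0, 3, 5))
  expect_equal(nrow(df), 3L)          # overlapping segments kept as-is
  expect_setequal(df$label, c("walking", "reaching_forward"))

  expect_error(writeSegments(ActionSegments(), p), NA)
  expect_error(ActionSegments(5, 5, "walking"), "start < end")
})

test_that("depth cache files split at 30 frames and reassemble", {
  p <- withr::local_tempfile(fileext = ".dcache")
  d <- randomDepthSeq(6, 5, 64, seed = 11)
  writeDepthCache(d, p)
  r <- readDepthCache(p)
  expect_identical(depthFrames(r), depthFrames(d))
})

test_that("label tracks round trip through TSV", {
  p <- withr::local_tempfile(fileext = ".tsv")
  tr <- FrameLabelTrack(rep(c("walking", "none_of_the_above"), c(4, 3)),
                        personId = c(1L, 1L, 1L, 1L, NA, NA, NA))
  writeLabelTrack(tr, p)
  r <- readLabelTrack(p)
  expect_identical(frameLabels(r), frameLabels(tr))
  expect_identical(r@personId, tr@personId)
})
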