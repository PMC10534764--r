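test_that("raw normals reproduce the hand-derived toy example", {
  img1 <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  arr <- array(c(img1, img1 + 1), dim = c(3, 3, 2))
  nl <- computeNormals(arr, normalize = FALSE)
  expect_equal(nrow(nl$normals), 1L)            # single interior pixel
  expect_equal(unname(nl$normals[1, ]), c(2, 6, -1, -1))
})

test_that("a constant sequence yields the degenerate flat normal", {
  arr <- array(500L, dim = c(4, 5, 3))
  nl <- computeNormals(arr)
  expect_equal(nrow(nl$normals), (3 - 1) * (4 - 2) * (5 - 2))
  expect_true(all(abs(sweep(nl$normals, 2, c(0, 0, 0, -1))) < 1e-12))
})

test_that("normal count is (T-1)(H-2)(W-2) and all normals are unit", {
  d <- randomDepthSeq(6, 7, 5, seed = 2)
  nl <- computeNormals(d)
  expect_equal(nrow(nl$normals), 4 * 4 * 5)
  expect_equal(unname(sqrt(rowSums(nl$normals^2))), rep(1, nrow(nl$normals)))
  expect_error(computeNormals(array(0, dim = c(4, 4, 1))), "2 frames")
})

test_that("projector set is the 120-vertex 600-cell, closed under negation", {
  P <- buildProjectors()
  expect_equal(nrow(P), 120L)
  expect_equal(unname(sqrt(rowSums(P^2))), rep(1, 120))
  for (i in seq_len(120)) {
    dists <- colSums((t(P) + P[i, ])^2)
    expect_lt(min(dists), 1e-18)               # -p present for every p
  }
  ## all vertices distinct
  expect_equal(nrow(unique(round(P, 9))), 120L)
})

test_that("histogram accumulation is max(0, dot) per bin", {
  P2 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  n <- matrix(c(0.6, 0.8, 0, 0), 1)
  expect_equal(accumulateHistogram(n, P2), c(0.6, 0.8))

  expect_equal(accumulateHistogram(matrix(numeric(0), 0, 4), P2), c(0, 0))

  P <- buildProjectors()
  h <- accumulateHistogram(P[17, , drop = FALSE], P)
  expect_equal(h[17], 1)                       # self-projection is 1
  neg <- which(P %*% P[17, ] < 0)
  expect_true(all(h[neg] == 0))                # negative dots clamp to 0

  ## invariant to normal ordering
  set.seed(3)
  N <- matrix(rnorm(40), 10, 4); N <- N / sqrt(rowSums(N^2))
  expect_equal(accumulateHistogram(N, P),
               accumulateHistogram(N[sample(10), ], P))
})

test_that("descriptor has the 4x4x3 x 120 layout and unit norm", {
  d <- randomDepthSeq(10, 10, 8, seed = 4)
  h <- hon4dDescriptor(d)
  expect_length(h, 4 * 4 * 3 * 120)
  expect_equal(sum(h^2), 1)
  expect_true(all(h >= 0))

  hs <- hon4dDescriptor(d, pool = "sum")
  expect_length(hs, 120L)
  expect_equal(sum(hs^2), 1)

  ## constant sequence: identical per-cell histograms
  dc <- DepthSequence(array(700L, dim = c(10, 10, 8)))
  hc <- matrix(hon4dDescriptor(dc), nrow = 120)   # one column per cell
  expect_true(max(apply(hc, 1, sd)) < 1e-12)      # identical across cells
  expect_gt(sum(hc[, 1] > 0), 0)                  # flat-normal bins light up

  expect_error(hon4dDescriptor(DepthSequence(array(0L, c(10, 10, 3)))),
               "temporal")
})

test_that("descriptor matches the naive triple-loop oracle on tiny inputs", {
  P <- buildProjectors()
  set.seed(11)
  for (case in 1:5) {
    h <- sample(6:8, 1); w <- sample(6:8, 1); T <- 4
    fr <- array(sample.int(3000, h * w * T, replace = TRUE), dim = c(h, w, T))
    expect_equal(as.vector(hon4dDescriptor(DepthSequence(fr))),
                 naiveHon4d(fr, projectors = P), tolerance = 1e-9)
  }
})

test_that("mirroring the input permutes the histogram bins accordingly", {
  ## flipping frames left-right negates the dx component of every normal;
  ## sign changes are symmetries of the 600-cell, so the histogram is
  ## permuted exactly (a coordinate swap, by contrast, is an odd
  ## permutation and not a symmetry of this vertex set)
  P <- buildProjectors()
  set.seed(12)
  fr <- array(sample.int(2000, 9 * 9 * 4, replace = TRUE), dim = c(9, 9, 4))
  frM <- fr[, 9:1, , drop = FALSE]
  h1 <- accumulateHistogram(computeNormals(fr)$normals, P)
  h2 <- accumulateHistogram(computeNormals(frM)$normals, P)
  Pflip <- P; Pflip[, 1] <- -Pflip[, 1]
  dists <- apply(Pflip, 1, function(v) min(colSums((t(P) - v)^2)))
  expect_lt(max(dists), 1e-18)   # sign flip maps vertices onto vertices
  perm <- apply(Pflip, 1, function(v) which.min(colSums((t(P) - v)^2)))
  expect_equal(h2, h1[perm], tolerance = 1e-9)
})

test_that("linear one-vs-rest classifier fits separable clip descriptors", {
  set.seed(20)
  centers <- diag(3)[, c(1, 2, 3)]
  X <- NULL; y <- c()
  for (k in 1:3) {
    X <- rbind(X, matrix(rnorm(20 * 3, 0, 0.05), 20, 3) +
                 matrix(centers[k, ], 20, 3, byrow = TRUE))
    y <- c(y, rep(letters[k], 20))
  }
  fit <- fitClipClassifier(X, y)
  expect_equal(mean(predictClip(fit, X) == y), 1)       # separable: perfect
  expect_equal(predictClip(fit, X[1, ]), y[1])
})

test_that("HON4D + classifier recognizes synthetic clips above chance", {
  classes <- setdiff(actionTaxonomy(), backgroundLabel())
  P <- buildProjectors()
  X <- NULL; y <- c()
  for (cl in classes) for (r in 1:6) {
    clip <- makeSkeletonClip(cl, 16, synthNoise(0, 0.008, 0.01),
                             r + 100 * match(cl, classes))
    d <- renderDepth(imputeJoints(clip$skeleton), synthCamera(),
                     synthNoise(15, 0, 0), r)
    X <- rbind(X, as.vector(hon4dDescriptor(d, projectors = P)))
    y <- c(y, cl)
  }
  heldOut <- rep(c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE), 5)
  fit <- fitClipClassifier(X[!heldOut, ], y[!heldOut])
  acc <- mean(predictClip(fit, X[heldOut, ]) == y[heldOut])
  expect_gt(acc, 0.2)                           # analytic chance level is 1/5
})
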