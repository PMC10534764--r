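## HON4D: histograms of oriented 4D surface normals (x, y, depth, time) for
## pre-segmented depth clips, with the 120 vertices of the 600-cell as
## histogram projectors, plus a linear one-vs-rest clip classifier.

#' Compute oriented 4D surface normals of a depth sequence
#'
#' For every interior pixel of frames 1..T-1 the raw normal is
#' (dz/dx, dz/dy, dz/dt, -1) with central spatial differences
#' (right - left, down - up) and the forward temporal difference
#' (current - next); each normal is then scaled to unit Euclidean norm. A
#' flat static surface yields the degenerate normal (0, 0, 0, -1), which
#' the constant -1 component keeps normalizable.
#'
#' @param depth a \linkS4class{DepthSequence} (or H x W x T array) with
#'   T >= 2 and H, W >= 3.
#' @param normalize unit-normalize the normals (default TRUE; FALSE returns
#'   the raw difference vectors).
#' @return list with \code{normals} (N x 4 matrix, columns dx, dy, dt, w)
#'   and \code{coords} (N x 3 matrix of 1-based x = column, y = row,
#'   t = frame indices), where N = (T-1)(H-2)(W-2).
#' @examples
#' d <- array(0L, dim = c(3, 3, 2))
#' computeNormals(DepthSequence(d))$normals  # all (0, 0, 0, -1)
#' @export
computeNormals <- function(depth, normalize = TRUE) {
  fr <- if (is(depth, "DepthSequence")) depth@frames else depth
  d <- dim(fr)
  H <- d[1L]; W <- d[2L]; T <- d[3L]
  if (T < 2L) stop("at least 2 frames are needed to compute 4D normals")
  if (H < 3L || W < 3L) stop("frames must be at least 3 x 3 pixels")
  ys <- 2L:(H - 1L); xs <- 2L:(W - 1L)
  nPix <- length(ys) * length(xs)
  N <- matrix(0, nPix * (T - 1L), 4L,
              dimnames = list(NULL, c("dx", "dy", "dt", "w")))
  coords <- matrix(0L, nPix * (T - 1L), 3L,
                   dimnames = list(NULL, c("x", "y", "t")))
  gy <- rep(ys, times = length(xs))
  gx <- rep(xs, each = length(ys))
  for (k in seq_len(T - 1L)) {
    f1 <- fr[, , k]; f2 <- fr[, , k + 1L]
    dx <- f1[ys, xs + 1L] - f1[ys, xs - 1L]
    dy <- f1[ys + 1L, xs] - f1[ys - 1L, xs]
    dt <- f1[ys, xs] - f2[ys, xs]
    rows <- (k - 1L) * nPix + seq_len(nPix)
    N[rows, ] <- cbind(as.vector(dx), as.vector(dy), as.vector(dt), -1)
    coords[rows, ] <- cbind(gx, gy, k)
  }
  if (normalize) N <- N / sqrt(rowSums(N^2))
  list(normals = N, coords = coords)
}

#' The 120 projectors: vertices of the regular 600-cell
#'
#' Histogram bins are the 120 unit vertices of the regular 600-cell
#' polychoron, uniformly covering directions in 4D: the 8 permutations of
#' (+/-1, 0, 0, 0), the 16 sign choices of (+/-1/2, +/-1/2, +/-1/2, +/-1/2),
#' and the 96 even permutations of (+/-phi, +/-1, +/-1/phi, 0)/2 with phi
#' the golden ratio. The set is closed under negation.
#'
#' @return a 120 x 4 matrix of unit row vectors.
#' @export
buildProjectors <- function() {
  phi <- (1 + sqrt(5)) / 2
  P <- matrix(0, 0, 4L)
  for (i in 1:4) for (s in c(1, -1)) {
    v <- numeric(4); v[i] <- s
    P <- rbind(P, v)
  }
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1), c(-1, 1)))
  P <- rbind(P, sgn / 2)
  perms <- permutations4()
  even <- perms[vapply(perms, permutationSign, 0) == 1]
  base <- c(phi / 2, 1 / 2, 1 / (2 * phi), 0)
  s3 <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  for (pm in even) {
    v <- base[order(pm)]        # place base values at permuted positions
    nz <- which(v != 0)
    for (r in seq_len(nrow(s3))) {
      w <- v; w[nz] <- w[nz] * s3[r, ]
      P <- rbind(P, w)
    }
  }
  P <- unique(round(P, 12))
  rownames(P) <- NULL
  P
}

permutations4 <- function() {
  out <- list()
  for (a in 1:4) for (b in 1:4) for (c in 1:4) for (d in 1:4)
    if (length(unique(c(a, b, c, d))) == 4L)
      out[[length(out) + 1L]] <- c(a, b, c, d)
  out
}

permutationSign <- function(p) {
  s <- 1
  for (i in 1:3) for (j in (i + 1):4) if (p[i] > p[j]) s <- -s
  s
}

#' Accumulate a histogram of oriented 4D normals
#'
#' Each bin k receives sum over normals n of max(0, p_k . n): positive dot
#' products vote for the projector's direction, negative ones contribute
#' nothing. Invariant to the ordering of the normals.
#'
#' @param normals N x 4 matrix of (unit) normals.
#' @param projectors B x 4 matrix of projectors (default the 600-cell set).
#' @param normalize L2-normalize the resulting histogram (default FALSE:
#'   raw accumulation as in the descriptor's inner loop).
#' @return numeric vector of length B.
#' @export
accumulateHistogram <- function(normals, projectors = buildProjectors(),
                                normalize = FALSE) {
  if (!nrow(normals)) return(numeric(nrow(projectors)))
  h <- colSums(pmax(normals %*% t(projectors), 0))
  if (normalize && sum(h^2) > 0) h <- h / sqrt(sum(h^2))
  h
}

#' HON4D descriptor of a depth clip
#'
#' Computes the oriented 4D normals of the clip, partitions the
#' (x, y, t) volume of interior pixels into a cells[1] x cells[2] x cells[3]
#' grid (width x height x time), accumulates a 120-bin histogram per cell,
#' L2-normalizes each cell histogram, concatenates them (cell order: x
#' fastest, then y, then t) and L2-normalizes the concatenation. With
#' \code{pool = "sum"} the per-cell histograms are instead summed into a
#' single 120-bin histogram before normalization.
#'
#' @param depth a \linkS4class{DepthSequence} (T >= 4 and at least
#'   (cells[2]+2) x (cells[1]+2) pixels for the default grid).
#' @param cells integer triple: cells along width, height, time
#'   (default c(4, 4, 3)).
#' @param pool \code{"concat"} (default, length prod(cells) * 120) or
#'   \code{"sum"} (length 120).
#' @param projectors projector matrix (default \code{buildProjectors()}).
#' @return numeric descriptor of unit L2 norm with attribute \code{grid}.
#' @export
hon4dDescriptor <- function(depth, cells = c(4L, 4L, 3L),
                            pool = c("concat", "sum"),
                            projectors = buildProjectors()) {
  pool <- match.arg(pool)
  fr <- if (is(depth, "DepthSequence")) depth@frames else depth
  d <- dim(fr)
  if (d[3L] - 1L < cells[3L])
    stop("too few frames for a ", cells[3L], "-slice temporal grid")
  if (d[1L] - 2L < cells[2L] || d[2L] - 2L < cells[1L])
    stop("frames too small for the spatial cell grid")
  nl <- computeNormals(fr)
  ## equal partitions of the interior coordinate ranges
  cellOf <- function(v, lo, hi, k) {
    pmin(k, pmax(1L, 1L + floor((v - lo) * k / (hi - lo + 1L))))
  }
  cx <- cellOf(nl$coords[, "x"], 2L, d[2L] - 1L, cells[1L])
  cy <- cellOf(nl$coords[, "y"], 2L, d[1L] - 1L, cells[2L])
  ct <- cellOf(nl$coords[, "t"], 1L, d[3L] - 1L, cells[3L])
  cellIdx <- cx + cells[1L] * (cy - 1L) + cells[1L] * cells[2L] * (ct - 1L)
  B <- nrow(projectors)
  nCells <- prod(cells)
  H <- matrix(0, nCells, B)
  for (ci in seq_len(nCells)) {
    sel <- cellIdx == ci
    if (any(sel))
      H[ci, ] <- accumulateHistogram(nl$normals[sel, , drop = FALSE],
                                     projectors)
  }
  if (pool == "concat") {
    nrm <- sqrt(rowSums(H^2))
    H <- H / ifelse(nrm > 0, nrm, 1)
    out <- as.vector(t(H))
  } else {
    out <- colSums(H)
  }
  n <- sqrt(sum(out^2))
  if (n > 0) out <- out / n
  attr(out, "grid") <- cells
  out
}

#' Linear one-vs-rest clip classifier over HON4D descriptors
#'
#' Fits one linear max-margin (SVM) machine per class against the rest;
#' prediction takes the class with the largest decision value. Decision
#' orientation is calibrated on the training data, so the result does not
#' depend on label ordering quirks of the underlying solver.
#'
#' @param x n x d matrix of descriptors (rows are clips).
#' @param labels character vector of clip labels.
#' @param cost SVM cost parameter.
#' @return model list of class \code{clipClassifier}.
#' @export
fitClipClassifier <- function(x, labels, cost = 10) {
  x <- as.matrix(x)
  classes <- sort(unique(labels))
  machines <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, "pos", "neg"), levels = c("pos", "neg"))
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")[, 1L]
    flip <- if (mean(dv[y == "pos"]) < mean(dv[y == "neg"])) -1 else 1
    list(fit = fit, flip = flip)
  })
  structure(list(classes = classes, machines = machines),
            class = "clipClassifier")
}

#' @rdname fitClipClassifier
#' @param model a fitted \code{clipClassifier}.
#' @export
predictClip <- function(model, x) {
  stopifnot(inherits(model, "clipClassifier"))
  if (is.null(dim(x))) x <- matrix(x, 1L)
  x <- as.matrix(x)
  scores <- vapply(model$machines, function(m) {
    dv <- attr(predict(m$fit, x, decision.values = TRUE),
               "decision.values")[, 1L]
    m$flip * dv
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  model$classes[max.col(scores, ties.method = "first")]
}
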