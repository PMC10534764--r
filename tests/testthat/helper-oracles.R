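# independent oracle: naive triple-loop HON4D for tiny sequences
naiveHon4d <- function(fr, cells = c(4L, 4L, 3L), projectors) {
  d <- dim(fr)
  raw <- list()
  for (k in seq_len(d[3] - 1)) for (x in 2:(d[2] - 1)) for (y in 2:(d[1] - 1)) {
    dx <- fr[y, x + 1, k] - fr[y, x - 1, k]
    dy <- fr[y + 1, x, k] - fr[y - 1, x, k]
    dt <- fr[y, x, k] - fr[y, x, k + 1]
    raw[[length(raw) + 1]] <- list(n = c(dx, dy, dt, -1), x = x, y = y, t = k)
  }
  nCells <- prod(cells)
  H <- matrix(0, nCells, nrow(projectors))
  for (r in raw) {
    n <- r$n / sqrt(sum(r$n^2))
    cx <- min(cells[1], 1 + floor((r$x - 2) * cells[1] / (d[2] - 2)))
    cy <- min(cells[2], 1 + floor((r$y - 2) * cells[2] / (d[1] - 2)))
    ct <- min(cells[3], 1 + floor((r$t - 1) * cells[3] / (d[3] - 1)))
    ci <- cx + cells[1] * (cy - 1) + cells[1] * cells[2] * (ct - 1)
    for (b in seq_len(nrow(projectors)))
      H[ci, b] <- H[ci, b] + max(0, sum(projectors[b, ] * n))
  }
  nrm <- sqrt(rowSums(H^2))
  H <- H / ifelse(nrm > 0, nrm, 1)
  v <- as.vector(t(H))
  v / sqrt(sum(v^2))
}

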