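## On-disk formats of the action logger: 16-bit depth PNG frames, compressed
## cache blocks, line-delimited skeleton streams, and TSV tracks/segments.

CACHE_MAGIC <- charToRaw("DTALCBLK")
CACHE_MAX_FRAMES <- 30L

crc32 <- function(bytes) .Call(C_crc32, bytes)

## fold an unsigned 32-bit value (stored as double) into R's signed integer
asI32 <- function(x) as.integer(ifelse(x >= 2^31, x - 2^32, x))

u32ToRaw <- function(x) writeBin(asI32(x), raw(), size = 4L,
                                 endian = "little")
rawToU32 <- function(r) {
  v <- readBin(r, "integer", n = length(r) %/% 4L, size = 4L,
               endian = "little")
  ifelse(v < 0, v + 2^32, as.numeric(v))
}

#' Read and write 16-bit millimeter depth PNG frames
#'
#' Depth frames are stored as single-channel 16-bit grayscale PNG with the
#' pixel value equal to the depth in millimeters (no rescaling), so the
#' sensor's native unit survives the round trip losslessly. Reading goes
#' through \code{png::readPNG}; writing uses the package's own minimal 16-bit
#' grayscale encoder because common R PNG writers emit 8-bit only.
#'
#' @param frame H x W matrix of integer depths in [0, 65535], millimeters.
#' @param path file path.
#' @return \code{writeDepthPNG} returns \code{path} invisibly;
#'   \code{readDepthPNG} returns the H x W integer millimeter matrix.
#' @examples
#' f <- matrix(0L, 4, 4); f[2, 3] <- 2500L
#' p <- tempfile(fileext = ".png")
#' writeDepthPNG(f, p)
#' identical(readDepthPNG(p), f)
#' @export
writeDepthPNG <- function(frame, path) {
  frame <- as.matrix(frame)
  if (any(frame < 0) || any(frame > 65535))
    stop("depth values must fit in 16 bits (0..65535)")
  if (any(frame != round(frame)))
    stop("depth values must be integral millimeters")
  h <- nrow(frame); w <- ncol(frame)
  ## scanlines: per image row, filter byte 0 then big-endian u16 samples
  sc <- matrix(as.raw(0), nrow = 2L * w + 1L, ncol = h)
  v <- as.integer(t(frame))                      # row-major sample order
  hi <- as.raw(v %/% 256L); lo <- as.raw(v %% 256L)
  sc[seq(2L, 2L * w, by = 2L), ] <- matrix(hi, nrow = w)
  sc[seq(3L, 2L * w + 1L, by = 2L), ] <- matrix(lo, nrow = w)
  idat <- memCompress(as.vector(sc), type = "gzip")   # zlib stream
  ihdr <- c(writeBin(c(w, h), raw(), size = 4L, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))
  chunk <- function(type, data) {
    body <- c(charToRaw(type), data)
    c(writeBin(length(data), raw(), size = 4L, endian = "big"), body,
      writeBin(asI32(crc32(body)), raw(), size = 4L, endian = "big"))
  }
  png <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           chunk("IHDR", ihdr), chunk("IDAT", idat), chunk("IEND", raw(0)))
  writeBin(png, path)
  invisible(path)
}

#' @rdname writeDepthPNG
#' @export
readDepthPNG <- function(path) {
  head <- readBin(path, "raw", n = 8L)
  if (length(head) < 8L ||
      !identical(head, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))))
    stop("not a PNG file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Pack and unpack logger cache blocks
#'
#' The logger batches up to 30 raw depth frames into one cache block: an
#' 8-byte magic, u32 frame count / height / width / payload length, a
#' zlib-compressed payload of little-endian u16 samples, and a CRC-32 tail
#' over the compressed payload for validation. The round trip is bit-exact
#' and any payload corruption is detected by the checksum.
#'
#' @param frames list of H x W integer millimeter matrices (1 to 30, uniform
#'   shape).
#' @param block raw vector as produced by \code{packCache}.
#' @return \code{packCache}: raw vector; \code{unpackCache}: list of H x W
#'   integer matrices.
#' @examples
#' b <- packCache(list(matrix(7L, 2, 2)))
#' unpackCache(b)
#' @export
packCache <- function(frames) {
  if (length(frames) < 1L) stop("cache block needs at least one frame")
  if (length(frames) > CACHE_MAX_FRAMES)
    stop("cache block capacity exceeded: at most ", CACHE_MAX_FRAMES,
         " frames per block")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("all frames in a block must share H x W")
  h <- dims[[1]][1L]; w <- dims[[1]][2L]
  v <- unlist(lapply(frames, as.vector), use.names = FALSE)
  if (any(v < 0) || any(v > 65535)) stop("depth values must fit in 16 bits")
  raw16 <- writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  payload <- memCompress(raw16, type = "gzip")
  c(CACHE_MAGIC, u32ToRaw(c(length(frames), h, w, length(payload))),
    payload, u32ToRaw(crc32(payload)))
}

#' @rdname packCache
#' @export
unpackCache <- function(block) {
  if (length(block) < 28L || !identical(block[1:8], CACHE_MAGIC))
    stop("not a cache block: bad magic")
  hdr <- rawToU32(block[9:24])
  n <- hdr[1L]; h <- hdr[2L]; w <- hdr[3L]; plen <- hdr[4L]
  if (length(block) != 24L + plen + 4L) stop("cache block truncated")
  payload <- block[25:(24L + plen)]
  tail <- rawToU32(block[(25L + plen):(28L + plen)])
  if (crc32(payload) != tail)
    stop("cache block checksum mismatch: payload corrupted")
  raw16 <- memDecompress(payload, type = "gzip")
  v <- readBin(raw16, "integer", n = n * h * w, size = 2L,
               endian = "little", signed = FALSE)
  lapply(seq_len(n), function(i)
    matrix(v[((i - 1L) * h * w + 1L):(i * h * w)], h, w))
}

#' Write / read a DepthSequence as consecutive cache blocks
#'
#' Splits the sequence into blocks of at most 30 frames (the logger's cache
#' size) and concatenates them into one \code{.dcache} file.
#'
#' @param depth a \linkS4class{DepthSequence}.
#' @param path file path.
#' @param fps frame rate to attach on read.
#' @return \code{readDepthCache} returns a \linkS4class{DepthSequence}.
#' @export
writeDepthCache <- function(depth, path) {
  fr <- depthFrames(depth)
  T <- dim(fr)[3L]
  starts <- seq(1L, T, by = CACHE_MAX_FRAMES)
  con <- file(path, "wb"); on.exit(close(con))
  for (s in starts) {
    idx <- s:min(s + CACHE_MAX_FRAMES - 1L, T)
    writeBin(packCache(lapply(idx, function(i) fr[, , i])), con)
  }
  invisible(path)
}

#' @rdname writeDepthCache
#' @export
readDepthCache <- function(path, fps = 8) {
  bytes <- readBin(path, "raw", n = file.size(path))
  frames <- list(); off <- 0L
  while (off < length(bytes)) {
    hdr <- rawToU32(bytes[(off + 9L):(off + 24L)])
    blen <- 28L + hdr[4L]
    frames <- c(frames, unpackCache(bytes[(off + 1L):(off + blen)]))
    off <- off + as.integer(blen)
  }
  arr <- array(0L, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  DepthSequence(arr, fps = fps)
}

#' Read and write skeleton streams
#'
#' Skeleton streams are serialized as line-delimited JSON, one record per
#' body per frame: timestamp (s), body id, 19 x 3 joint coordinates (m),
#' 19 x 2 image projections (px), and 4 floor-plane coefficients. Reading
#' groups records by body id into per-body \linkS4class{SkeletonSequence}
#' objects ordered by timestamp.
#'
#' @param skeletons a \linkS4class{SkeletonSequence} or list of them.
#' @param path file path (conventionally \code{.jsonl}).
#' @return \code{readSkeletonStream}: list of \linkS4class{SkeletonSequence},
#'   one per body id present (empty list for an empty file).
#' @export
writeSkeletonStream <- function(skeletons, path) {
  if (is(skeletons, "SkeletonSequence")) skeletons <- list(skeletons)
  recs <- list()
  for (sk in skeletons) {
    for (t in seq_len(nFrames(sk))) {
      recs[[length(recs) + 1L]] <- list(
        ts = sk@timestamps[t], body = sk@bodyId,
        j3 = unname(sk@joints[t, , ]), j2 = unname(sk@joints2d[t, , ]),
        floor = sk@floorPlane)
    }
  }
  ord <- order(vapply(recs, `[[`, 0, "ts"),
               vapply(recs, `[[`, 0L, "body"))
  lines <- vapply(recs[ord], function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17), na = "null"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSkeletonStream
#' @export
readSkeletonStream <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  recs <- lapply(lines, jsonlite::fromJSON)
  for (r in recs) {
    if (is.null(dim(r$j3)) || nrow(r$j3) != 19L || ncol(r$j3) != 3L)
      stop("skeleton record violates the 19-joint schema")
  }
  bodies <- sort(unique(vapply(recs, `[[`, 0, "body")))
  lapply(bodies, function(b) {
    sub <- recs[vapply(recs, `[[`, 0, "body") == b]
    sub <- sub[order(vapply(sub, `[[`, 0, "ts"))]
    T <- length(sub)
    j3 <- array(0, dim = c(T, 19L, 3L)); j2 <- array(NA_real_, c(T, 19L, 2L))
    for (t in seq_len(T)) {
      j3[t, , ] <- sub[[t]]$j3
      j2t <- sub[[t]]$j2
      if (!is.null(dim(j2t))) j2[t, , ] <- j2t
    }
    SkeletonSequence(j3, j2, timestamps = vapply(sub, `[[`, 0, "ts"),
                     bodyId = as.integer(b),
                     floorPlane = as.numeric(sub[[1]]$floor))
  })
}

#' Read and write action segment tables
#'
#' Tab-separated with a header: columns \code{start}, \code{end},
#' \code{label}, \code{person_id}, \code{score}; frame coordinates are
#' 0-based half-open. Segments are written sorted by start frame and
#' preserved as-is otherwise (overlaps are not merged).
#'
#' @param segments an \linkS4class{ActionSegments}.
#' @param path file path.
#' @return \code{readSegments} returns an \linkS4class{ActionSegments}.
#' @export
writeSegments <- function(segments, path) {
  df <- segmentTable(segments)
  if (nrow(df) && any(df$end <= df$start))
    stop("segments must satisfy start < end")
  df <- df[order(df$start, df$end), , drop = FALSE]
  out <- data.frame(start = df$start, end = df$end, label = df$label,
                    person_id = df$personId, score = df$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSegments
#' @export
readSegments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) && any(df$end <= df$start))
    stop("segment file contains an empty or inverted interval")
  df <- df[order(df$start, df$end), , drop = FALSE]
  ActionSegments(df$start, df$end, df$label, df$score, df$person_id)
}

#' Read and write per-frame label tracks
#'
#' Tab-separated with a header: columns \code{frame} (0-based),
#' \code{label}, \code{person_id}.
#'
#' @param track a \linkS4class{FrameLabelTrack}.
#' @param path file path.
#' @return \code{readLabelTrack} returns a \linkS4class{FrameLabelTrack}.
#' @export
writeLabelTrack <- function(track, path) {
  out <- data.frame(frame = seq_along(track@labels) - 1L,
                    label = track@labels, person_id = track@personId)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelTrack
#' @export
readLabelTrack <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$frame), , drop = FALSE]
  FrameLabelTrack(df$label, df$person_id)
}
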