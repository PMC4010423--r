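#' @include AllClasses.R
NULL

#' Read and write streamlines in TCK format
#'
#' MRtrix-style track files: a text header followed by little-endian float32
#' point triplets, one NaN triplet between streamlines and an Inf triplet at
#' the end of the stream. Coordinates are written in voxel space (the
#' package-wide convention); the header records this together with the
#' emitted count, termination statuses and seed voxels, so a round trip
#' restores the full [StreamlineSet] (point coordinates to float32 precision,
#' better than 1e-5 voxel units at phantom scale). Voxel paths are
#' reconstructed from segment midpoints, which is exact except for voxels the
#' streamline only clipped for less than float32 resolution: such
#' micro-visits may drop from the reconstructed path.
#'
#' @param streams A [StreamlineSet] with stored points.
#' @param path File path (conventionally `.tck`).
#' @return `writeTracks()` returns `path` invisibly; `readTracks()` a
#'   [StreamlineSet].
#' @export
writeTracks <- function(streams, path) {
  stopifnot(is(streams, "StreamlineSet"))
  n <- length(streams)
  if (n > 0L && !length(streams@points))
    stop("streamline set carries no point coordinates")
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", n),
              "icetrack_space: voxel",
              sprintf("icetrack_dims: %s", paste(streams@dims, collapse = ",")),
              sprintf("icetrack_n_emitted: %d", streams@nEmitted),
              sprintf("icetrack_status: %s",
                      paste(streams@status, collapse = ",")),
              sprintf("icetrack_seed_voxel: %s",
                      paste(streams@seedVoxel, collapse = ",")),
              sprintf("icetrack_stream_id: %s",
                      paste(streams@streamId, collapse = ",")))
  # the offset line changes the header length; fix by iteration
  offset <- 0L
  for (k in 1:3) {
    lines <- c(header, sprintf("file: . %d", offset), "END", "")
    need <- nchar(paste(lines, collapse = "\n"), type = "bytes")
    if (need <= offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste(lines, collapse = "\n"), con, eos = NULL)
  pad <- offset - need
  if (pad > 0L) writeChar(strrep("\n", pad), con, eos = NULL)
  sep <- rep(NaN, 3L)
  for (i in seq_len(n)) {
    pts <- streams@points[[i]]
    writeBin(as.numeric(t(pts)), con, size = 4L, endian = "little")
    writeBin(sep, con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname writeTracks
#' @param dims Grid dimensions, required when the file lacks the
#'   `icetrack_dims` header field.
#' @export
readTracks <- function(path, dims = NULL) {
  if (!file.exists(path)) stop("no such track file: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  magic <- rawToChar(raw[1:13])
  if (!identical(magic, "mrtrix tracks"))
    stop("not a TCK file (bad magic): ", path)
  # parse header text up to END
  endPat <- charToRaw("\nEND\n")
  headEnd <- NA_integer_
  for (i in seq_len(min(length(raw) - 4L, 65536L))) {
    if (raw[i] == endPat[1L] && identical(raw[i + 1:4], endPat[2:5])) {
      headEnd <- i + 4L
      break
    }
  }
  if (is.na(headEnd)) stop("TCK header END marker not found")
  hdr <- strsplit(rawToChar(raw[seq_len(headEnd)]), "\n")[[1L]]
  getField <- function(key) {
    ln <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^", key, ": "), "", ln[1L])
  }
  dtype <- getField("datatype")
  if (!is.null(dtype) && dtype != "Float32LE")
    stop("unsupported TCK datatype: ", dtype)
  fileField <- getField("file")
  if (is.null(fileField)) stop("TCK header lacks a file offset")
  offset <- as.integer(sub("^\\. ", "", fileField))
  vals <- readBin(raw[(offset + 1L):length(raw)], "numeric",
                  n = (length(raw) - offset) %/% 4L, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  endRow <- which(is.infinite(m[, 1L]))[1L]
  if (is.na(endRow)) stop("TCK stream terminator missing")
  m <- m[seq_len(endRow - 1L), , drop = FALSE]
  breaks <- which(is.nan(m[, 1L]))
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, nrow(m))
  keep <- starts <= ends
  pts <- Map(function(s, e) m[s:e, , drop = FALSE], starts[keep], ends[keep])
  n <- length(pts)

  if (!is.null(getField("icetrack_dims")))
    dims <- as.integer(strsplit(getField("icetrack_dims"), ",")[[1L]])
  if (is.null(dims)) stop("grid dimensions not in header; supply dims=")
  dims <- .checkDims(dims)
  paths <- lapply(pts, function(p) {
    # every inter-point segment lies inside a single voxel (FACT steps run
    # face to face), so segment midpoints recover the interior voxels exactly;
    # the two terminal points sit just inside their voxels (a nudge float32
    # may have swallowed), so round them with a small bias along the travel
    # direction
    if (nrow(p) >= 2L) {
      n <- nrow(p)
      d <- diff(p)
      d <- d / pmax(sqrt(rowSums(d^2)), 1e-12)
      mids <- (p[-n, , drop = FALSE] + p[-1L, , drop = FALSE]) / 2
      pts2 <- p
      pts2[1L, ] <- p[1L, ] - 1e-4 * d[1L, ]
      pts2[n, ] <- p[n, ] + 1e-4 * d[n - 1L, ]
      v <- matrix(0, 2L * n - 1L, 3L)
      v[seq(1L, 2L * n - 1L, by = 2L), ] <- round(pts2)
      v[seq(2L, 2L * n - 2L, by = 2L), ] <- round(mids)
    } else v <- round(p)
    v <- pmin(pmax(v, 1), matrix(dims, nrow(v), 3L, byrow = TRUE))
    keepRow <- if (nrow(v) < 2L) TRUE else
      c(TRUE, rowSums(abs(diff(v))) > 0)
    .lin(v[keepRow, , drop = FALSE], dims)
  })
  parseInts <- function(key, default) {
    f <- getField(key)
    if (is.null(f)) rep(default, n) else as.integer(strsplit(f, ",")[[1L]])
  }
  status <- parseInts("icetrack_status", 1L)
  seedVoxel <- parseInts("icetrack_seed_voxel", NA_integer_)
  if (anyNA(seedVoxel) && n > 0L)
    seedVoxel <- vapply(paths, `[`, integer(1L), 1L)
  streamId <- parseInts("icetrack_stream_id", 0L)
  nEmitted <- getField("icetrack_n_emitted")
  nEmitted <- if (is.null(nEmitted)) n else as.integer(nEmitted)
  StreamlineSet(dims = dims, paths = paths, points = pts,
                status = status, seedVoxel = seedVoxel,
                streamId = streamId, nEmitted = max(nEmitted, n))
}
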