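#' Write streamlines to a TrackVis-style (.trk) or MRtrix-style (.tck) file
#'
#' `.trk`: the fixed 1000-byte TrackVis header followed by per-track point
#' counts and float32 coordinates; coordinates are stored in world mm.
#' `.tck`: the textual MRtrix header followed by float32 triplets with NaN
#' track separators and an Inf terminator.  Round-trips preserve
#' coordinates to float32 precision (well within 1e-4 mm for desk-scale
#' geometry).
#'
#' @param set a `streamline_set`.
#' @param path output path; the dialect is chosen by extension unless
#'   `dialect` is given.
#' @param dialect `"trk"` or `"tck"` (default: from the file extension).
#' @return invisibly, `path`.
#' @export
write_streamlines <- function(set, path, dialect = NULL) {
  stopifnot(inherits(set, "streamline_set"))
  if (is.null(dialect))
    dialect <- if (grepl("\\.tck$", path)) "tck" else "trk"
  if (dialect == "trk") write_trk(set, path) else write_tck(set, path)
  invisible(path)
}

write_trk <- function(set, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               raw(n - min(length(raw), n))), con)
  }
  wi <- function(x, size = 4L) writeBin(as.integer(x), con, size = size,
                                        endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  vs <- rep(set$voxel_size, length.out = 3)
  wc("TRACK", 6)
  wi(rep(0L, 3), 2)                  # dim (unknown)
  wf(vs)                             # voxel_size
  wf(c(0, 0, 0))                     # origin
  wi(0L, 2); writeBin(raw(10 * 20), con)   # n_scalars + names
  wi(0L, 2); writeBin(raw(10 * 20), con)   # n_properties + names
  vox2ras <- diag(c(vs, 1))
  wf(as.numeric(t(vox2ras)))
  writeBin(raw(444), con)            # reserved
  wc("LPS", 4); writeBin(raw(4), con)      # voxel_order, pad2
  wf(c(1, 0, 0, 0, 1, 0)); writeBin(raw(2), con)  # orientation, pad1
  writeBin(raw(6), con)              # invert/swap flags
  wi(length(set$streamlines))        # n_count
  wi(2L)                             # version
  wi(1000L)                          # hdr_size
  for (m in set$streamlines) {
    wi(nrow(m))
    wf(as.numeric(t(m)))
  }
  invisible(path)
}

write_tck <- function(set, path) {
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(set$streamlines)),
           "meniscusdti: deterministic tensor tracking")
  # the offset counts the header including the offset line itself
  base <- sum(nchar(hdr) + 1L) + nchar("file: . ") + nchar("END") + 1L + 1L
  off <- NA_integer_
  for (d in 1:10) if (nchar(as.character(base + d)) == d) {
    off <- base + d
    break
  }
  off_line <- sprintf("file: . %d", off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, off_line, "END"), con, sep = "\n")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  for (m in set$streamlines) {
    wf(as.numeric(t(m)))
    wf(rep(NaN, 3))
  }
  wf(rep(Inf, 3))
  invisible(path)
}

#' Read streamlines from a .trk or .tck file
#'
#' @param path input path.
#' @param dialect `"trk"` or `"tck"` (default: from the file extension).
#' @return a `streamline_set`.
#' @export
read_streamlines <- function(path, dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.tck$", path)) "tck" else "trk"
  if (dialect == "trk") read_trk(path) else read_tck(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6)
  if (!identical(rawToChar(magic[1:5]), "TRACK"))
    stop("format error: not a TrackVis track file")
  ri <- function(n, size = 4L) readBin(con, "integer", n = n, size = size,
                                       endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4L, endian = "little")
  invisible(ri(3, 2))
  vs <- rf(3)
  invisible(rf(3))
  n_scalars <- ri(1, 2); invisible(readBin(con, "raw", n = 200))
  n_props <- ri(1, 2); invisible(readBin(con, "raw", n = 200))
  invisible(rf(16)); invisible(readBin(con, "raw", n = 444))
  invisible(readBin(con, "raw", n = 8)); invisible(rf(6))
  invisible(readBin(con, "raw", n = 2 + 6))
  n_count <- ri(1)
  version <- ri(1)
  hdr_size <- ri(1)
  if (!identical(hdr_size, 1000L)) stop("format error: malformed trk header")
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- ri(1)
    if (length(np) == 0) stop("format error: truncated trk body")
    pts <- rf(np * (3 + n_scalars))
    m <- matrix(pts, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    if (n_props > 0) invisible(rf(n_props))
    sl[[i]] <- m
  }
  structure(list(streamlines = sl, seed_index = rep(NA_integer_, n_count),
                 voxel_size = vs[1], origin = c(0, 0, 0), params = NULL),
            class = "streamline_set")
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  if (!identical(first, "mrtrix tracks"))
    stop("format error: not an mrtrix track file")
  offset <- NA_integer_
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("format error: malformed tck header")
    if (identical(ln, "END")) break
    if (grepl("^file: \\. ", ln))
      offset <- as.integer(sub("^file: \\. ", "", ln))
  }
  if (is.na(offset)) stop("format error: tck header lacks a file offset")
  seek(con, where = offset, origin = "start")
  vals <- readBin(con, "double", n = file.size(path), size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  sl <- list()
  cur <- NULL
  for (i in seq_len(nrow(m))) {
    if (all(is.infinite(m[i, ]))) break
    if (all(is.nan(m[i, ]))) {
      if (!is.null(cur)) sl[[length(sl) + 1L]] <- cur
      cur <- NULL
    } else cur <- rbind(cur, m[i, ])
  }
  structure(list(streamlines = sl,
                 seed_index = rep(NA_integer_, length(sl)),
                 voxel_size = 1, origin = c(0, 0, 0), params = NULL),
            class = "streamline_set")
}
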