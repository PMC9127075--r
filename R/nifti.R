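#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes uncompressed single-file NIfTI-1 (`.nii`) volumes with a
#' diagonal RAS sform built from the voxel size and origin.  Covers exactly
#' what this package needs: 3D/4D arrays of uint8, int16, int32, float32 or
#' float64 data on an axis-aligned grid.  The world coordinate of 1-based
#' voxel index `v` along axis `k` is `(v - 1) * voxel_size[k] + origin[k]`
#' (voxel-centre convention).
#'
#' @param img numeric or integer array, 3 or 4 dimensional.
#' @param path output path ending in `.nii`.
#' @param voxel_size length-3 voxel edge lengths, mm.
#' @param origin length-3 world coordinate of the first voxel centre, mm.
#' @param datatype one of `"auto"`, `"uint8"`, `"int16"`, `"int32"`,
#'   `"float32"`, `"float64"`.  `"auto"` picks int32 for integer-valued
#'   arrays and float32 otherwise.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1),
                        origin = c(0, 0, 0), datatype = "auto") {
  d <- dim(img)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("img must be a 3D or 4D array")
  if (datatype == "auto")
    datatype <- if (is.integer(img)) "int32" else "float32"
  dt <- switch(datatype,
    uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L),
    int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L),
    int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L),
    float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L),
    float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L),
    stop("unsupported datatype: ", datatype))
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               raw(n - min(length(raw), n))), con)
  }
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  pixdim8 <- c(1, voxel_size, rep(1, 7 - length(d)),
               rep(0, length(d) - 3))[1:8]
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name (unused)
  wi(0L, 4); wi(0L, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1-3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(pixdim8)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); wc("", 1); wc(rawToChar(as.raw(10L)), 1)  # slice_end, slice_code, xyzt_units (mm|s)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("meniscusdti", 80); wc("", 24)
  wi(0L, 2); wi(1L, 2)             # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern_b/c/d, qoffset
  wf(c(voxel_size[1], 0, 0, origin[1]))
  wf(c(0, voxel_size[2], 0, origin[2]))
  wf(c(0, 0, voxel_size[3], origin[3]))
  wc("", 16)
  wc("n+1", 4)
  writeBin(raw(4), con)            # extension flag
  writeBin(
    if (dt$what == "integer") as.integer(img) else as.double(img),
    con, size = dt$size, endian = "little")
  invisible(path)
}

#' @rdname write_nifti
#' @return `read_nifti` returns a list with `data` (array), `voxel_size`,
#'   `origin`, and `datatype`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size) readBin(con, "integer", n = n, size = size,
                                  endian = "little")
  rf <- function(n) readBin(con, "double", n = n, size = 4L, endian = "little")
  hdr_size <- ri(1, 4)
  if (!identical(hdr_size, 348L)) stop("format error: not a NIfTI-1 file")
  invisible(readBin(con, "raw", n = 36))       # through dim_info
  dim8 <- ri(8, 2)
  invisible(rf(3)); invisible(ri(1, 2))        # intent
  dtcode <- ri(1, 2); invisible(ri(2, 2))      # datatype, bitpix, slice_start
  pixdim <- rf(8)
  vox_offset <- rf(1)
  scl_slope <- rf(1); scl_inter <- rf(1)
  invisible(readBin(con, "raw", n = 2 + 1 + 1))
  invisible(rf(4)); invisible(ri(2, 4))
  invisible(readBin(con, "raw", n = 104))      # descrip + aux_file
  invisible(ri(2, 2))                          # qform, sform codes
  invisible(rf(6))
  srow <- matrix(rf(12), 3, 4, byrow = TRUE)
  seek(con, where = vox_offset, origin = "start")
  nd <- dim8[1]
  d <- dim8[2:(1 + nd)]
  n <- prod(d)
  dt <- switch(as.character(dtcode),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code: ", dtcode))
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = d),
       voxel_size = pixdim[2:4],
       origin = srow[, 4],
       datatype = dtcode)
}
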