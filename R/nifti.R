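# Minimal NIfTI-1 reader/writer (.nii / .nii.gz). No NIfTI package ships
# with the target environment, and the format's single-file variant is a
# fixed 348-byte header plus a raw voxel block, so the subset needed here
# (3D volumes, float/int datatypes, pixdim spacing, sform affine,
# scl_slope/inter scaling, either endianness on read) is implemented
# directly.

.nii_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param x 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing mm per voxel along each axis.
#' @param affine Optional 4x4 voxel-to-world matrix (row-major srow storage);
#'   defaults to `diag(c(spacing, 1))`.
#' @param dtype `"float64"`, `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1), affine = NULL,
                        dtype = c("float64", "float32", "uint8")) {
  dtype <- match.arg(dtype)
  d <- dim(x)
  stopifnot(length(d) == 3, length(spacing) == 3)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  code <- switch(dtype, float64 = 64L, float32 = 16L, uint8 = 2L)
  bitpix <- switch(dtype, float64 = 64L, float32 = 32L, uint8 = 8L)
  con <- .nii_open(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                      # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0L, 4); wi(0L, 2)             # extents, session_error
  writeBin(charToRaw("r"), con)    # regular
  writeBin(as.raw(0L), con)        # dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2) # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)        # intent_p1..3, intent_code
  wi(code, 2); wi(bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))    # pixdim[8]
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 2L)), con)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  wc("wavetta", 80); wc("", 24)    # descrip, aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern b,c,d; qoffset x,y,z
  wf(affine[1, ]); wf(affine[2, ]); wf(affine[3, ])  # srow_x/y/z
  wc("", 16)
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)            # extension indicator
  if (dtype == "uint8") {
    writeBin(as.raw(as.integer(x)), con)
  } else {
    writeBin(as.numeric(x), con, size = bitpix / 8, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List: `data` (3D array, scl slope/intercept applied), `spacing`
#'   (pixdim mm triple), `affine` (4x4; sform if present, else spacing
#'   diagonal).
#' @export
read_nifti <- function(path) {
  con <- .nii_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("corrupt NIfTI header (short read): ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("corrupt NIfTI header (sizeof_hdr != 348): ", path)
  }
  ri <- function(off, size, n = 1) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  }
  rf <- function(off, n = 1) {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  }
  dims <- ri(40, 2, 8)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1)) {
    stop("only 3D NIfTI volumes are supported; got dim = ",
         paste(dims[2:(1 + max(ndim, 1))], collapse = "x"))
  }
  d <- dims[2:4]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112)
  scl_inter <- rf(116)
  sform_code <- ri(254, 2)
  srow <- rbind(rf(280, 4), rf(296, 4), rf(312, 4), c(0, 0, 0, 1))
  n <- prod(d)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    `2` = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    `4` = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    `8` = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    `16` = readBin(con, "double", n = n, size = 4, endian = endian),
    `64` = readBin(con, "double", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  if (length(data) < n) stop("corrupt NIfTI voxel block (short read): ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  dim(data) <- d
  spacing <- pixdim[2:4]
  affine <- if (sform_code > 0) srow else diag(c(spacing, 1))
  list(data = data, spacing = spacing, affine = affine)
}
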