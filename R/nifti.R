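# Minimal NIfTI-1 reader/writer.
#
# The pre-installed R stack has no NIfTI package, so the small subset of
# NIfTI-1 this pipeline needs (2-D/3-D single-file .nii / .nii.gz,
# little-endian, float32/float64/int8/int16/int32) is implemented here and
# was cross-checked against nibabel. Matrix rows map to the first (x) voxel
# dimension.

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 2-D image (or 3-D array) as a NIfTI-1 file
#'
#' @param img Numeric matrix or 3-d array.
#' @param path Output path; `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default) or `"int16"`. Masks and unit-range
#'   images survive either; int16 stores `round(img * 1000)` with a scale
#'   slope, i.e. a quantization of 1e-3.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, datatype = c("float32", "int16")) {
  datatype <- match.arg(datatype)
  d <- dim(img)
  if (is.null(d) || length(d) > 3L) stop("img must be 2-d or 3-d", call. = FALSE)
  dim8 <- rep(1L, 8L)
  dim8[1L] <- length(d)
  dim8[seq_along(d) + 1L] <- d

  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  pad <- function(n) writeBin(raw(n), con)

  code <- if (datatype == "float32") c(16L, 32L) else c(4L, 16L)
  slope <- if (datatype == "float32") 1 else 1e-3

  wi(348L, 4L)                  # sizeof_hdr
  pad(36L)                      # data_type, db_name, extents, session_error, regular, dim_info
  wi(dim8, 2L)                  # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)    # intent_p1-3, intent_code
  wi(code[1L], 2L)              # datatype
  wi(code[2L], 2L)              # bitpix
  wi(0L, 2L)                    # slice_start
  wf(c(0, rep(1, 7)))           # pixdim (pixdim[0] unused)
  wf(352)                       # vox_offset
  wf(slope); wf(0)              # scl_slope, scl_inter
  wi(0L, 2L); pad(2L)           # slice_end, slice_code + xyzt_units
  wf(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)             # glmax, glmin
  pad(104L)                     # descrip, aux_file
  wi(c(0L, 1L), 2L)             # qform_code, sform_code
  wf(rep(0, 6))                 # quatern b/c/d, qoffset x/y/z
  wf(c(1, 0, 0, 0,  0, 1, 0, 0,  0, 0, 1, 0))  # srow_x/y/z (identity)
  pad(16L)                      # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); pad(1L)
  pad(4L)                       # no extensions
  if (datatype == "float32") {
    writeBin(as.numeric(img), con, size = 4L, endian = "little")
  } else {
    writeBin(as.integer(round(img / slope)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any plain single-file
#' little-endian NIfTI-1 volume)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A matrix (2-d image) or array, with scale slope/intercept applied.
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  ri <- function(off, size, n = 1L) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  }
  rf <- function(off, n = 1L) {
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = "little")
  }
  if (ri(0L, 4L) != 348L) stop("not a little-endian NIfTI-1 file: ", path,
                               call. = FALSE)
  dim8 <- ri(40L, 2L, 8L)
  d <- dim8[2L:(1L + dim8[1L])]
  datatype <- ri(70L, 2L)
  vox_offset <- rf(108L)
  slope <- rf(112L); inter <- rf(116L)
  if (slope == 0) slope <- 1

  n <- prod(d)
  readBin(con, "raw", as.integer(vox_offset) - 348L)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE))
  out <- array(vals * slope + inter, dim = d)
  if (length(d) == 2L) out <- matrix(out, d[1L], d[2L])
  out
}

#' Export an image as a plain-text PGM (or PNG if available)
#'
#' Inspection helper: writes an 8-bit grayscale rendering of a unit-range image.
#' PNG needs the optional `png` package; PGM (text format `P2`) needs
#' nothing.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.pgm` or `.png`.
#' @return `path`, invisibly.
#' @export
write_image_preview <- function(img, path) {
  v <- pmin(pmax(img, 0), 1)
  if (grepl("\\.png$", path)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is not installed; use a .pgm path", call. = FALSE)
    }
    png::writePNG(v, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
  write(as.integer(t(round(v * 255))), con, ncolumns = 16L)  # row-major raster
  invisible(path)
}
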