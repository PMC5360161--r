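#' Minimal NIfTI-1 input/output
#'
#' Self-contained reader/writer for single-file NIfTI-1 (`.nii`, `.nii.gz`)
#' volumes. Supports the datatypes this pipeline emits and consumes
#' (uint8 masks, int16/float32/float64 signal and ADC volumes), the
#' `scl_slope`/`scl_inter` intensity scaling fields, and an sform affine
#' built from the voxel spacing (RAS+, axis-aligned). Byte order is detected
#' from `sizeof_hdr`; files are always written little-endian.
#'
#' This is deliberately not a general NIfTI implementation: no qform
#' quaternions, no extensions, no >3D time series.
#'
#' @name nifti_io
NULL

.nifti_dtypes <- list(
  uint8   = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L,  bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L,  bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D array as a NIfTI-1 volume
#'
#' @param x 3D numeric or logical array.
#' @param path output file; `.nii` or `.nii.gz`.
#' @param spacing voxel spacing in mm, length 3.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`. Logical input defaults to `"uint8"`, numeric to `"float32"`.
#' @param description free-text tag stored in the header (max 79 chars).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, spacing = c(1, 1, 1),
                        datatype = if (is.logical(x)) "uint8" else "float32",
                        description = "adctrack") {
  stopifnot(is.array(x), length(dim(x)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  datatype <- match.arg(datatype, names(.nifti_dtypes))
  dt <- .nifti_dtypes[[datatype]]
  dims <- dim(x)

  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw[seq_len(min(length(raw), n))],
               raw(n - min(length(raw), n))), con)
  }

  wi(348L, 4)                                  # sizeof_hdr
  writeBin(raw(36L), con)                      # data_type, db_name, extents,
                                               # session_error, regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)           # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                    # intent_p1..p3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, spacing, 1, 1, 1, 1))                # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                        # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2L), con)            # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)          # cal_max/min, slice_dur, toffset,
                                               # glmax, glmin
  wc(description, 80L); wc("", 24L)            # descrip, aux_file
  wi(c(0L, 1L), 2)                             # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                      # quatern_b/c/d, qoffset_x/y/z
  wf(c(spacing[1], 0, 0, 0))                   # srow_x
  wf(c(0, spacing[2], 0, 0))                   # srow_y
  wf(c(0, 0, spacing[3], 0))                   # srow_z
  wc("", 16L)                                  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                       # extension flag: none

  vals <- as.vector(x)
  if (dt$what == "integer") {
    storage <- as.integer(round(vals))
    writeBin(storage, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (3D array, intensity-scaled if the header says so),
#'   `spacing` (mm), `datatype`, and `description`.
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)

  ri <- function(off, size, n = 1L, endian = "little", signed = TRUE) {
    readBin(hdr[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, endian = endian, signed = signed)
  }
  rf <- function(off, n = 1L, endian = "little") {
    readBin(hdr[(off + 1L):(off + 4L * n)], "double",
            n = n, size = 4L, endian = endian)
  }

  endian <- "little"
  if (ri(0L, 4L) != 348L) {
    if (ri(0L, 4L, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "'")

  dim0 <- ri(40L, 2L, n = 8L, endian = endian)
  ndim <- dim0[1]
  if (ndim < 3L) stop("expected a 3D volume, got dim = ", ndim)
  dims <- dim0[2:4]
  if (ndim > 3L && any(dim0[5:(ndim + 1)] > 1L))
    stop("4D+ volumes are not supported")

  dcode <- ri(70L, 2L, endian = endian)
  dt_idx <- vapply(.nifti_dtypes, function(d) d$code == dcode, logical(1))
  if (!any(dt_idx)) stop("unsupported NIfTI datatype code ", dcode)
  datatype <- names(.nifti_dtypes)[dt_idx]
  dt <- .nifti_dtypes[[datatype]]

  pixdim <- rf(76L, n = 8L, endian = endian)
  vox_offset <- rf(108L, endian = endian)
  scl_slope <- rf(112L, endian = endian)
  scl_inter <- rf(116L, endian = endian)
  descrip <- sub("\\x00.*$", "", rawToChar(hdr[149:228]))

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  endian = endian, signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  list(data = array(vals, dim = dims),
       spacing = pixdim[2:4],
       datatype = datatype,
       description = descrip)
}
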