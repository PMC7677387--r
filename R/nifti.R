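# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in this R stack, so the format is handled
# directly.  Scope: single-file uncompressed or gzipped ".nii"/".nii.gz",
# 3-d images, little- or big-endian, datatypes uint8/int8/int16/uint16/
# int32/float32/float64, scl_slope/scl_inter applied on read.  Written
# files carry an sform (code 1) whose diagonal encodes the voxel size in
# mm, datatype float64 for intensity volumes and uint8 for masks.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a list with `data` (3-d numeric array), `voxel_mm` (length-3
#'   voxel size in mm, from the sform when present, else pixdim) and
#'   `datatype` (NIfTI datatype code)
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L)
    stop("not a NIfTI-1 file (", path, "): header truncated")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (", path, "): sizeof_hdr != 348")
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (", path, "): bad magic '", magic, "'")
  if (magic == "ni1")
    stop("two-file NIfTI (.hdr/.img) is not supported: ", path)

  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1):(off + n * size)], what, n, size, endian = endian)
  dim16      <- rd(40, "integer", 8L, 2L)
  datatype   <- rd(70, "integer", 1L, 2L)
  pixdim     <- rd(76, "double", 8L, 4L)
  vox_offset <- rd(108, "double", 1L, 4L)
  scl_slope  <- rd(112, "double", 1L, 4L)
  scl_inter  <- rd(116, "double", 1L, 4L)
  sform_code <- rd(254, "integer", 1L, 2L)
  srow <- rbind(rd(280, "double", 4L, 4L),
                rd(296, "double", 4L, 4L),
                rd(312, "double", 4L, 4L))

  ndim <- dim16[1]
  if (ndim < 3L || ndim > 4L)
    stop("unsupported NIfTI dimensionality (dim[0] = ", ndim, ") in ", path)
  dims <- dim16[2:4]
  nvol <- if (ndim == 4L && dim16[5] > 1L)
    stop("4-d NIfTI with multiple volumes is not supported: ", path) else 1L

  spec <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(spec))
    stop("unsupported NIfTI datatype code ", datatype, " in ", path)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims) * nvol
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(data) < n) stop("NIfTI data truncated in ", path)
  data <- as.double(data)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  dim(data) <- dims

  voxel_mm <- if (sform_code > 0L) {
    sqrt(colSums(srow[, 1:3, drop = FALSE]^2))
  } else {
    abs(pixdim[2:4])
  }
  list(data = data, voxel_mm = voxel_mm, datatype = datatype)
}

#' Write a 3-d array as NIfTI-1
#'
#' @param data 3-d numeric array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param voxel_mm length-3 voxel size in mm
#' @param datatype NIfTI datatype code: 64 (float64, default) or 2 (uint8)
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, path, voxel_mm, datatype = 64L) {
  stopifnot(length(dim(data)) == 3L, length(voxel_mm) == 3L,
            all(voxel_mm > 0), datatype %in% c(2L, 64L))
  dims <- dim(data)

  hc <- rawConnection(raw(0), "wb")
  wb <- function(x, size) writeBin(x, hc, size = size, endian = "little")
  pad <- function(n) writeBin(raw(n), hc)
  wb(348L, 4L)                       # sizeof_hdr
  pad(36)                            # data_type..regular, dim_info
  wb(as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim
  pad(12)                            # intent_p1..p3
  wb(0L, 2L)                         # intent_code
  wb(as.integer(datatype), 2L)       # datatype
  wb(if (datatype == 2L) 8L else 64L, 2L)          # bitpix
  wb(0L, 2L)                         # slice_start
  wb(c(1, voxel_mm, 1, 1, 1, 1), 4L) # pixdim (qfac = 1)
  wb(352, 4L)                        # vox_offset
  wb(c(1, 0), 4L)                    # scl_slope, scl_inter
  wb(0L, 2L)                         # slice_end
  pad(1)                             # slice_code
  writeBin(as.raw(2L), hc)           # xyzt_units = mm
  wb(c(0, 0, 0, 0), 4L)              # cal_max/min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                  # glmax, glmin
  pad(80 + 24)                       # descrip, aux_file
  wb(c(0L, 1L), 2L)                  # qform_code = 0, sform_code = 1
  wb(rep(0, 6), 4L)                  # quaternion, qoffset
  srow <- rbind(c(voxel_mm[1], 0, 0, 0),
                c(0, voxel_mm[2], 0, 0),
                c(0, 0, voxel_mm[3], 0))
  wb(as.numeric(t(srow)), 4L)        # srow_x/y/z
  pad(16)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), hc)        # magic
  writeBin(raw(4), hc)               # no extensions
  hdr <- rawConnectionValue(hc)
  close(hc)
  stopifnot(length(hdr) == 352L)

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  if (datatype == 2L) {
    vals <- as.integer(round(as.vector(data)))
    if (any(vals < 0 | vals > 255)) stop("uint8 data out of range")
    writeBin(as.raw(vals), con)
  } else {
    writeBin(as.numeric(data), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Construct a Dixon water-signal volume
#'
#' A 3-d non-negative intensity field on a regular grid.  Axis convention:
#' axes 1-2 are in-plane (left-right, anterior-posterior), axis 3 runs
#' inferior to superior.
#'
#' @param data 3-d numeric array of signal intensities (finite, >= 0)
#' @param voxel_mm physical voxel size per axis in mm
#'   (default `c(2.232, 2.232, 3.0)`, the working resolution of the
#'   resampled Dixon acquisition)
#' @return an object of class `dixon_volume`
#' @export
dixon_volume <- function(data, voxel_mm = c(2.232, 2.232, 3.0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-d array")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  if (length(voxel_mm) != 3L || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("'voxel_mm' must be three positive numbers")
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm)),
            class = "dixon_volume")
}

#' @export
print.dixon_volume <- function(x, ...) {
  cat(sprintf("<dixon_volume> %s voxels @ %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_mm, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Construct a binary muscle mask
#'
#' @param data 3-d array of 0/1 values on the same grid as its volume
#' @param voxel_mm physical voxel size per axis in mm
#' @return an object of class `muscle_mask`
#' @export
muscle_mask <- function(data, voxel_mm = c(2.232, 2.232, 3.0)) {
  if (length(dim(data)) != 3L) stop("'data' must be a 3-d array")
  if (!is_binary_array(data)) stop("mask must be binary (0/1)")
  structure(list(data = data, voxel_mm = as.numeric(voxel_mm)),
            class = "muscle_mask")
}

#' @export
print.muscle_mask <- function(x, ...) {
  cat(sprintf("<muscle_mask> %s voxels, %d foreground (%.1f ml)\n",
              paste(dim(x$data), collapse = "x"), sum(x$data),
              sum(x$data) * prod(x$voxel_mm) / 1000))
  invisible(x)
}

#' Read a Dixon volume from NIfTI
#' @param path path to a NIfTI file
#' @return a [dixon_volume()]
#' @export
read_volume <- function(path) {
  nii <- read_nifti(path)
  dixon_volume(pmax(nii$data, 0), nii$voxel_mm)
}

#' Read a binary mask from NIfTI
#' @param path path to a NIfTI file; values are binarized at 0.5
#' @return a [muscle_mask()]
#' @export
read_mask <- function(path) {
  nii <- read_nifti(path)
  muscle_mask((nii$data >= 0.5) * 1L, nii$voxel_mm)
}

#' Write a Dixon volume to NIfTI (float64)
#' @param volume a [dixon_volume()]
#' @param path output path
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "dixon_volume"))
  write_nifti(volume$data, path, volume$voxel_mm, 64L)
}

#' Write a binary mask to NIfTI (uint8 0/1)
#' @param mask a [muscle_mask()]
#' @param path output path
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "muscle_mask"))
  write_nifti(mask$data, path, mask$voxel_mm, 2L)
}
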