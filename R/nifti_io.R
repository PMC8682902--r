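# Minimal single-file NIfTI-1 (.nii) I/O.
#
# No NIfTI package can be assumed at run time, so the 348-byte NIfTI-1
# header is read and written directly. Supported on-disk datatypes: uint8
# (2), int16 (4), int32 (8), float32 (16), float64 (64); both endiannesses
# are read, little-endian is written. Integer HU volumes round-trip
# losslessly as int16.

NIFTI_DATATYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L))

#' Write a CT volume as NIfTI-1
#'
#' @param volume a \code{\link{ct_volume}}.
#' @param path output path (conventionally \code{.nii}).
#' @param datatype on-disk type: \code{"int16"} (default; HU values are
#'   rounded), \code{"float32"} or \code{"float64"}.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(volume, path, datatype = c("int16", "float32",
                                                    "float64")) {
  stopifnot(inherits(volume, "ct_volume"))
  datatype <- match.arg(datatype)
  code <- c(int16 = 4L, float32 = 16L, float64 = 64L)[[datatype]]
  data <- volume$voxels
  if (datatype == "int16") {
    data <- round(data)
    if (any(data < -32768 | data > 32767))
      stop("values out of int16 range; use a float datatype", call. = FALSE)
  }
  .write_nifti(data, dim(volume$voxels), volume$pitch, code, path)
  invisible(path)
}

#' Write a binary mask as NIfTI-1 (uint8)
#'
#' @param mask logical 3D array, or a \code{\link{threshold_segment}} result.
#' @param path output path.
#' @param pitch voxel pitch in mm (scalar or length 3).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path, pitch) {
  if (inherits(mask, "segmentation_result")) mask <- mask$mask
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (length(pitch) == 1L) pitch <- rep(pitch, 3L)
  .write_nifti(mask * 1L, dim(mask), pitch, 2L, path)
  invisible(path)
}

.write_nifti <- function(data, dims, pitch, datatype_code, path) {
  dt <- NIFTI_DATATYPES[[as.character(datatype_code)]]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4L) writeBin(as.double(x), con, size = size,
                                        endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                              # sizeof_hdr
  wraw(36L)                                 # data_type..regular, dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2L)       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                # intent_p1..3, intent_code
  wi(datatype_code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L)
  wf(c(1, pitch, rep(0, 4)))                # pixdim[8]
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); wraw(2L)                      # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                         # cal_max..toffset
  wi(c(0L, 0L), 4L)                         # glmax, glmin
  wraw(104L)                                # descrip, aux_file
  wi(c(0L, 0L), 2L)                         # qform_code, sform_code
  wf(rep(0, 6))                             # quatern, qoffset
  wf(c(pitch[1], 0, 0, 0,  0, pitch[2], 0, 0,  0, 0, pitch[3], 0))
  wraw(16L)                                 # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)   # magic
  wraw(4L)                                  # extension flag
  storage.mode(data) <- if (dt$what == "integer") "integer" else "double"
  writeBin(as.vector(data), con, size = dt$size, endian = "little")
}

#' Read a NIfTI-1 volume as a CT volume
#'
#' Accepts single-file uncompressed \code{.nii}. Anisotropic pitch is
#' accepted with a warning (per-axis pitch retained); float volumes whose
#' values fall outside the conventional HU range [-1000, 1000] raise a
#' range warning rather than an error.
#'
#' @param path path to a \code{.nii} file.
#' @return a \code{\link{ct_volume}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header", call. = FALSE)
  rd <- function(off, what, n, size, endian, signed = TRUE)
    readBin(hdr_raw[(off + 1L):length(hdr_raw)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, "little") != 348L) {
    if (rd(0L, "integer", 1L, 4L, "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic)", call. = FALSE)
  dim8 <- rd(40L, "integer", 8L, 2L, endian)
  if (dim8[1] < 3L) stop("expected a 3D volume", call. = FALSE)
  dims <- dim8[2:4]
  datatype <- rd(70L, "integer", 1L, 2L, endian)
  dt <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)
  pixdim <- rd(76L, "double", 8L, 4L, endian)
  pitch <- pixdim[2:4]
  if (any(!is.finite(pitch)) || any(pitch <= 0))
    stop("missing or invalid pixel-size metadata (pixdim)", call. = FALSE)
  vox_offset <- rd(108L, "double", 1L, 4L, endian)
  scl_slope <- rd(112L, "double", 1L, 4L, endian)
  scl_inter <- rd(116L, "double", 1L, 4L, endian)
  seek(con, where = vox_offset, origin = "start")
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n) stop("truncated NIfTI data section", call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  ct_volume(array(data, dim = dims), pitch = pitch)
}
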