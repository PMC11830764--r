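# Minimal NIfTI-1 single-file (.nii) I/O. No R NIfTI package is assumed;
# this codec covers exactly what the pipeline needs: 3D/4D arrays,
# little-endian write, endian-detecting read, no compression, no
# extensions, identity-scaled voxels.

.NIFTI_DTYPES <- data.frame(
  name   = c("uint8", "int16", "int32", "float32", "float64"),
  code   = c(2L, 4L, 8L, 16L, 64L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

#' Write a 3D or 4D array as NIfTI-1
#'
#' @param img Numeric 3D or 4D array.
#' @param path Output file path (conventionally `.nii`).
#' @param datatype Storage type. `float64` round-trips R doubles exactly;
#'   `int32`/`uint8` are for masks and label fields.
#' @param pixdim Voxel size triple; purely informational here (the
#'   synthetic grids have no world-space semantics).
#' @return The path, invisibly.
#' @export
write_nifti <- function(img, path,
                        datatype = c("float64", "float32", "int32", "int16", "uint8"),
                        pixdim = c(1, 1, 1)) {
  datatype <- match.arg(datatype)
  dims <- dim(img)
  if (is.null(dims) || !(length(dims) %in% 3:4)) {
    stop("img must be a 3D or 4D array")
  }
  dt <- .NIFTI_DTYPES[.NIFTI_DTYPES$name == datatype, ]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wi(348L, 4L)                                   # sizeof_hdr
  writeBin(raw(28L), con)                        # data_type, db_name
  wi(0L, 4L); wi(0L, 2L)                         # extents, session_error
  writeBin(as.raw(c(114L, 0L)), con)             # regular = 'r', dim_info
  d <- rep(1L, 8L); d[1L] <- length(dims); d[1L + seq_along(dims)] <- dims
  wi(d, 2L)                                      # dim
  wf(c(0, 0, 0)); wi(0L, 2L)                     # intent_p1-3, intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L) # datatype, bitpix, slice_start
  pd <- c(1, pixdim, if (length(dims) == 4L) 1 else 0, 0, 0, 0)
  wf(pd[1:8])                                    # pixdim
  wf(352); wf(1); wf(0)                          # vox_offset, scl_slope, scl_inter
  wi(0L, 2L); writeBin(raw(2L), con)             # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                              # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                              # glmax, glmin
  writeBin(raw(104L), con)                       # descrip, aux_file
  wi(c(0L, 1L), 2L)                              # qform_code, sform_code
  wf(rep(0, 6))                                  # quatern_b/c/d, qoffset_x/y/z
  wf(c(pixdim[1L], 0, 0, 0))
  wf(c(0, pixdim[2L], 0, 0))
  wf(c(0, 0, pixdim[3L], 0))                     # srow
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con) # magic
  writeBin(raw(4L), con)                         # extension indicator
  v <- as.vector(img)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.double(v), con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(v), con, size = dt$bitpix / 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path Path to an uncompressed single-file NIfTI-1 image.
#' @return List with `data` (array), `datatype` (NIfTI code) and `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, 4L, endian = "little")
  endian <- if (identical(sz, 348L)) "little" else "big"
  seek(con, 40L)
  dims8 <- readBin(con, "integer", 8L, 2L, endian = endian)
  seek(con, 70L)
  code <- readBin(con, "integer", 1L, 2L, endian = endian)
  seek(con, 76L)
  pixdim8 <- readBin(con, "numeric", 8L, 4L, endian = endian)
  seek(con, 108L)
  vox_offset <- readBin(con, "numeric", 1L, 4L, endian = endian)
  slope <- readBin(con, "numeric", 1L, 4L, endian = endian)
  inter <- readBin(con, "numeric", 1L, 4L, endian = endian)
  seek(con, 344L)
  magic <- rawToChar(readBin(con, "raw", 3L))
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file: ", path)
  ndim <- dims8[1L]
  if (ndim < 3L || ndim > 4L) stop("unsupported NIfTI dimensionality: ", ndim)
  dims <- dims8[2L:(1L + ndim)]
  n <- prod(dims)
  seek(con, vox_offset)
  data <- switch(as.character(code),
    "2"  = as.numeric(readBin(con, "integer", n, 1L, signed = FALSE, endian = endian)),
    "4"  = as.numeric(readBin(con, "integer", n, 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n, 4L, endian = endian)),
    "16" = readBin(con, "numeric", n, 4L, endian = endian),
    "64" = readBin(con, "numeric", n, 8L, endian = endian),
    stop("unsupported NIfTI datatype code: ", code)
  )
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  if (!is.na(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    data <- data * slope + inter
  }
  list(data = array(data, dims), datatype = code, pixdim = pixdim8[2:4])
}
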