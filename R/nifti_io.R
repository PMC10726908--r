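# Minimal single-file NIfTI-1 I/O.
#
# Covers exactly what this pipeline needs: uncompressed or gzipped .nii,
# 3-D or 4-D volumes, float32/float64/int16/uint8/int32 data, voxel sizes
# from pixdim, scl_slope/scl_inter applied on read. No orientation
# handling beyond pixdim (the pipeline consumes already-aligned volumes).

nifti_dtypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE))    # float64

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return List with `data` (array), `voxel_size` (mm, length 3) and
#'   `dim`.
#' @export
read_nifti <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L)
  swap <- sizeof_hdr != 348L
  endian <- if (swap) "swap" else .Platform$endian
  if (swap) {
    sizeof_hdr <- 348L  # re-read everything in swapped order below
  }
  rb <- function(what, n, size) readBin(con, what, n, size = size,
                                        endian = endian, signed = TRUE)
  invisible(readBin(con, "raw", 36L))            # unused header fields
  dims <- rb("integer", 8L, 2L)
  invisible(rb("double", 3L, 4L))                # intent parameters
  invisible(rb("integer", 1L, 2L))               # intent_code
  datatype <- rb("integer", 1L, 2L)
  invisible(rb("integer", 1L, 2L))               # bitpix
  invisible(rb("integer", 1L, 2L))               # slice_start
  pixdim <- rb("double", 8L, 4L)
  vox_offset <- rb("double", 1L, 4L)
  scl_slope <- rb("double", 1L, 4L)
  scl_inter <- rb("double", 1L, 4L)
  nd <- dims[1]
  shape <- dims[2:(1 + max(nd, 1L))]
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop_param("unsupported NIfTI datatype code ", datatype)
  # skip to vox_offset (we are at byte 120)
  invisible(readBin(con, "raw", as.integer(vox_offset) - 120L))
  n <- prod(shape)
  data <- readBin(con, dt$what, n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  list(data = array(data, dim = shape),
       voxel_size = pixdim[2:4], dim = shape)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3-D or 4-D numeric array.
#' @param path Output path; `.gz` suffix selects gzip compression.
#' @param voxel_size Voxel edge lengths (dx, dy, dz) in mm.
#' @param datatype `"float32"`, `"float64"`, `"int16"` or `"uint8"`.
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1),
                        datatype = c("float32", "float64", "int16",
                                     "uint8")) {
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L,
                 uint8 = 2L)
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int16 = 16L,
                   uint8 = 8L)
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% 3:4))
    stop_param("data must be a 3-D or 4-D array")
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wb_i <- function(x, size) writeBin(as.integer(x), con, size = size)
  wb_d <- function(x, size) writeBin(as.double(x), con, size = size)
  wb_i(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(36L), con)                         # data_type..dim_info
  dims <- integer(8L)
  dims[1] <- length(d)
  dims[2:(1 + length(d))] <- d
  dims[dims == 0L] <- 1L
  dims[1] <- length(d)
  wb_i(dims, 2L)
  wb_d(c(0, 0, 0), 4L); wb_i(0L, 2L)              # intent
  wb_i(code, 2L); wb_i(bitpix, 2L); wb_i(0L, 2L)  # datatype/bitpix/slice
  wb_d(c(1, voxel_size, rep(1, 4))[1:8], 4L)      # pixdim
  wb_d(352, 4L)                                   # vox_offset
  wb_d(1, 4L); wb_d(0, 4L)                        # scl_slope / scl_inter
  writeBin(raw(4L), con)                          # slice_end/code, xyzt
  wb_d(c(max(data), min(data)), 4L)               # cal_max / cal_min
  wb_d(c(0, 0), 4L); wb_i(c(0L, 0L), 4L)          # slice_dur, toffset, glmax/min
  writeBin(charToRaw(sprintf("%-80s", "t2pools")), con)   # descrip
  writeBin(raw(24L), con)                         # aux_file
  wb_i(c(0L, 1L), 2L)                             # qform_code, sform_code=1
  wb_d(c(0, 0, 0, 0, 0, 0), 4L)                   # quaternions
  wb_d(c(voxel_size[1], 0, 0, 0), 4L)             # srow_x
  wb_d(c(0, voxel_size[2], 0, 0), 4L)             # srow_y
  wb_d(c(0, 0, voxel_size[3], 0), 4L)             # srow_z
  writeBin(raw(16L), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4L), con)                          # extension flag
  if (datatype %in% c("int16", "uint8")) {
    wb_i(round(data), switch(datatype, int16 = 2L, uint8 = 1L))
  } else {
    wb_d(data, switch(datatype, float32 = 4L, float64 = 8L))
  }
  invisible(path)
}
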