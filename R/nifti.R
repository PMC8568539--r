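# Minimal single-file NIfTI-1 (.nii, uncompressed) reader/writer.
# Covers what the package needs: 2-D/3-D arrays, voxel spacing in the
# header, common datatypes. No NIfTI package is available in the target
# environment, hence this small self-contained implementation.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE))

#' Write a 2-D/3-D array as an uncompressed NIfTI-1 file
#'
#' The voxel spacing goes into `pixdim`; orientation is identity with the
#' origin at (0, 0, 0) (qform/sform code 0), which is sufficient for
#' viewing exported label volumes at correct physical scale.
#'
#' @param data numeric 2-D or 3-D array
#' @param path output path (conventionally `.nii`)
#' @param pixdim voxel spacing in mm, one value per data dimension
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64)
#' @export
write_nifti <- function(data, path, pixdim = rep(1, 3), datatype = 16L) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 2 || nd > 3) stop("write_nifti: need 2-D or 3-D data")
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("write_nifti: unsupported datatype ", datatype)
  pixdim <- rep_len(as.numeric(pixdim), nd)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  dims <- c(nd, dim(data), rep(1L, 7 - nd))
  wi(dims, 2)                                   # dim[8]
  writeBin(raw(14), con)                        # intent_p1..intent_code
  wi(datatype, 2)                               # datatype
  wi(8L * dt$size, 2)                           # bitpix
  wi(0L, 2)                                     # slice_start
  wf(c(1, pixdim, rep(1, 7 - nd)))              # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(1); wf(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(1), con); writeBin(raw(1), con)  # slice_end/code/xyzt
  wf(0); wf(0); wf(0); wf(0)                    # cal_max/min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 0L), 2)                              # qform_code, sform_code
  wf(rep(0, 18))                                # quatern/qoffset + srow
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  v <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(v)), con, size = dt$size, endian = "little")
  } else writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  invisible(path)
}

#' Read an uncompressed NIfTI-1 file
#'
#' @param path path to a `.nii` file
#' @return list with `data` (array) and `pixdim` (voxel spacing, mm)
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 348) stop("read_nifti: truncated header in ", path)
  endian <- "little"
  gi <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = signed, endian = endian)
  if (gi(0, 4) != 348L) {
    endian <- "big"
    if (gi(0, 4) != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: bad magic in ", path)
  dim8 <- gi(40, 2, 8)
  nd <- dim8[1]
  dims <- dim8[2:(1 + nd)]
  datatype <- gi(70, 2)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("read_nifti: unsupported datatype ", datatype)
  gf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4, endian = endian)
  pixdim <- gf(76, 8)[2:(1 + nd)]
  vox_offset <- gf(108)
  skip <- vox_offset - 352
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  v <- readBin(con, dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = endian)
  slope <- gf(112); inter <- gf(116)
  if (slope != 0 && !(slope == 1 && inter == 0)) v <- v * slope + inter
  list(data = array(v, dim = dims), pixdim = pixdim)
}
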