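# Minimal DICOM reader/writer: explicit-VR little-endian, single-frame,
# uncompressed 16-bit CT slices. Only the tags needed for HU conversion,
# geometry and ordering are interpreted; everything else is skipped.
# No DICOM library exists in the target environment.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

DCM_LONG_VR <- c("OB", "OW", "OF", "SQ", "UT", "UN")

read_dicom_element <- function(con) {
  tagraw <- readBin(con, "raw", 4)
  if (length(tagraw) < 4) return(NULL)
  group <- readBin(tagraw[1:2], "integer", size = 2, signed = FALSE, endian = "little")
  element <- readBin(tagraw[3:4], "integer", size = 2, signed = FALSE, endian = "little")
  vr <- rawToChar(readBin(con, "raw", 2))
  if (!grepl("^[A-Z]{2}$", vr))
    stop("unsupported DICOM encoding (implicit VR?) at tag ", dcm_tag(group, element))
  if (vr %in% DCM_LONG_VR) {
    readBin(con, "raw", 2)  # reserved
    len <- readBin(con, "integer", size = 4, endian = "little")
  } else {
    len <- readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
  }
  value <- if (len > 0) readBin(con, "raw", len) else raw(0)
  list(tag = dcm_tag(group, element), vr = vr, value = value)
}

dcm_str <- function(el) sub(" +$", "", rawToChar(el$value[el$value != as.raw(0)]))
dcm_num <- function(el) as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])
dcm_us <- function(el) readBin(el$value, "integer", size = 2, signed = FALSE,
                               endian = "little")

#' Read one single-frame CT DICOM file
#'
#' Supports explicit-VR little-endian files. Pixel values are converted to
#' Hounsfield units via the stored rescale slope and intercept; missing
#' rescale tags are an error naming the tag.
#'
#' @param path path to a `.dcm` file
#' @return a [ct_slice()]
#' @export
read_dicom <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM") {
    close(con); on.exit()
    con <- file(path, "rb")
    on.exit(close(con))
  }
  els <- list()
  repeat {
    el <- read_dicom_element(con)
    if (is.null(el)) break
    els[[el$tag]] <- el
    if (el$tag == "7FE0,0010") break
  }
  need <- function(tag, what) {
    if (is.null(els[[tag]]))
      stop("DICOM file ", path, " is missing required tag (", tag, ") ", what)
    els[[tag]]
  }
  rows <- dcm_us(need("0028,0010", "Rows"))
  cols <- dcm_us(need("0028,0011", "Columns"))
  slope <- dcm_num(need("0028,1053", "RescaleSlope"))
  inter <- dcm_num(need("0028,1052", "RescaleIntercept"))
  spacing <- dcm_num(need("0028,0030", "PixelSpacing"))
  bits <- if (!is.null(els[["0028,0100"]])) dcm_us(els[["0028,0100"]]) else 16L
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- !is.null(els[["0028,0103"]]) && dcm_us(els[["0028,0103"]]) == 1L
  thick <- if (!is.null(els[["0018,0050"]])) dcm_num(els[["0018,0050"]]) else NA_real_
  z <- if (!is.null(els[["0020,0032"]])) dcm_num(els[["0020,0032"]])[3]
       else if (!is.null(els[["0020,1041"]])) dcm_num(els[["0020,1041"]])
       else NA_real_
  px <- need("7FE0,0010", "PixelData")
  stored <- readBin(px$value, "integer", n = rows * cols, size = 2,
                    signed = signed, endian = "little")
  hu <- matrix(stored, nrow = rows, ncol = cols, byrow = TRUE) * slope + inter
  ct_slice(hu, pixel_spacing_mm = spacing, slice_thickness_mm = thick,
           z_position_mm = z, source_id = path)
}

#' Read a directory of single-frame CT DICOM files as an ordered series
#'
#' Slices are ordered by z-position. Slices with inconsistent shape or
#' pixel spacing (a mixed series) are an error.
#'
#' @param path directory containing `.dcm` files (any extension; all
#'   regular files are tried)
#' @return list of [ct_slice()], ordered by increasing z
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files found in ", path)
  slices <- lapply(files, read_dicom)
  shapes <- vapply(slices, function(s) paste(dim(s$pixels), collapse = "x"), "")
  spac <- vapply(slices, function(s) paste(s$pixel_spacing_mm, collapse = ","), "")
  if (length(unique(shapes)) > 1 || length(unique(spac)) > 1)
    stop("mixed DICOM series in ", path, ": inconsistent shape or spacing")
  z <- vapply(slices, function(s) s$z_position_mm, 0)
  if (anyNA(z)) stop("DICOM series in ", path, " lacks z positions")
  slices[order(z)]
}

dcm_write_element <- function(con, group, element, vr, value) {
  writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
  writeChar(vr, con, nchars = 2, eos = NULL)
  if (vr %in% DCM_LONG_VR) {
    writeBin(raw(2), con)
    writeBin(length(value), con, size = 4, endian = "little")
  } else {
    writeBin(length(value), con, size = 2, endian = "little")
  }
  if (length(value)) writeBin(value, con)
}

dcm_pad <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2) r <- c(r, as.raw(0x20))
  r
}

#' Write a CT slice as a single-frame DICOM file
#'
#' Explicit-VR little-endian, 16-bit signed pixels. HU values are stored
#' with rescale intercept -1024 and slope 1.
#'
#' @param slice a [ct_slice()]
#' @param path output path
#' @export
write_dicom <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  ts <- dcm_pad("1.2.840.10008.1.2.1")
  # file meta group: group length + transfer syntax
  meta_len <- 8L + length(ts)
  dcm_write_element(con, 0x0002, 0x0000, "UL",
                    writeBin(meta_len, raw(), size = 4, endian = "little"))
  dcm_write_element(con, 0x0002, 0x0010, "UI", ts)
  num <- function(x) dcm_pad(paste(format(x, trim = TRUE, scientific = FALSE),
                                   collapse = "\\"))
  intercept <- -1024
  stored <- round(slice$pixels - intercept)
  stored <- pmin(pmax(stored, -32768), 32767)
  dcm_write_element(con, 0x0008, 0x0060, "CS", dcm_pad("CT"))
  if (!is.na(slice$z_position_mm))
    dcm_write_element(con, 0x0020, 0x0032, "DS", num(c(0, 0, slice$z_position_mm)))
  if (!is.na(slice$slice_thickness_mm))
    dcm_write_element(con, 0x0018, 0x0050, "DS", num(slice$slice_thickness_mm))
  dcm_write_element(con, 0x0028, 0x0002, "US",
                    writeBin(1L, raw(), size = 2, endian = "little"))
  dcm_write_element(con, 0x0028, 0x0010, "US",
                    writeBin(nrow(slice$pixels), raw(), size = 2, endian = "little"))
  dcm_write_element(con, 0x0028, 0x0011, "US",
                    writeBin(ncol(slice$pixels), raw(), size = 2, endian = "little"))
  dcm_write_element(con, 0x0028, 0x0030, "DS", num(slice$pixel_spacing_mm))
  for (spec in list(c(0x0100, 16L), c(0x0101, 16L), c(0x0102, 15L), c(0x0103, 1L)))
    dcm_write_element(con, 0x0028, spec[1], "US",
                      writeBin(as.integer(spec[2]), raw(), size = 2, endian = "little"))
  dcm_write_element(con, 0x0028, 0x1052, "DS", num(intercept))
  dcm_write_element(con, 0x0028, 0x1053, "DS", num(1))
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  dcm_write_element(con, 0x7FE0, 0x0010, "OW", px)
  invisible(path)
}
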