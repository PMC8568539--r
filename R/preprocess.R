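#' CT slice container
#'
#' One 2-D CT image in Hounsfield units with acquisition metadata.
#'
#' @param pixels numeric matrix of HU values (finite)
#' @param pixel_spacing_mm length-2 positive numeric (row, column spacing)
#' @param slice_thickness_mm optional positive scalar
#' @param z_position_mm optional scalar slice position
#' @param source_id opaque identifier string
#' @return object of class `ct_slice`
#' @export
ct_slice <- function(pixels, pixel_spacing_mm,
                     slice_thickness_mm = NA_real_,
                     z_position_mm = NA_real_,
                     source_id = "") {
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) stop("ct_slice: pixels must be finite")
  pixel_spacing_mm <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(pixel_spacing_mm <= 0)) stop("ct_slice: spacing must be positive")
  structure(list(pixels = pixels, pixel_spacing_mm = pixel_spacing_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 z_position_mm = z_position_mm,
                 source_id = source_id),
            class = "ct_slice")
}

#' CT display window
#'
#' Window width and center (level) in HU. The defaults are the soft-tissue
#' window used for kidney segmentation: width 420 HU, center 60 HU.
#'
#' @param width_hu positive window width
#' @param center_hu window center (level)
#' @export
window_setting <- function(width_hu = 420, center_hu = 60) {
  if (width_hu <= 0) stop("window width must be positive")
  structure(list(width_hu = width_hu, center_hu = center_hu),
            class = "window_setting")
}

#' Window a CT slice and normalize to [0, 1]
#'
#' Clips HU values to `[center - width/2, center + width/2]` and maps the
#' window linearly onto `[0, 1]`; this mapping is also the network's input
#' normalization (no per-image statistics are used).
#'
#' @param slice a [ct_slice()] or a plain HU matrix
#' @param w a [window_setting()]
#' @return numeric matrix with values in `[0, 1]`
#' @export
window_and_normalize <- function(slice, w = window_setting()) {
  x <- if (inherits(slice, "ct_slice")) slice$pixels else as.matrix(slice)
  lo <- w$center_hu - w$width_hu / 2
  pmin(pmax((x - lo) / w$width_hu, 0), 1)
}

# Separable index maps for resampling an n_in grid onto n_out, aligning
# pixel centers ((i - 0.5) / n scale convention).
resample_coords <- function(n_in, n_out) {
  (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
}

bilinear_resize <- function(img, target) {
  ri <- resample_coords(nrow(img), target[1])
  ci <- resample_coords(ncol(img), target[2])
  r0 <- pmin(pmax(floor(ri), 1), nrow(img)); r1 <- pmin(r0 + 1, nrow(img))
  c0 <- pmin(pmax(floor(ci), 1), ncol(img)); c1 <- pmin(c0 + 1, ncol(img))
  fr <- pmin(pmax(ri - r0, 0), 1); fc <- pmin(pmax(ci - c0, 0), 1)
  a <- img[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
       img[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
       img[r0, c1, drop = FALSE] * outer(1 - fr, fc) +
       img[r1, c1, drop = FALSE] * outer(fr, fc)
  a
}

nearest_resize <- function(img, target) {
  ri <- pmin(pmax(round(resample_coords(nrow(img), target[1])), 1), nrow(img))
  ci <- pmin(pmax(round(resample_coords(ncol(img), target[2])), 1), ncol(img))
  img[ri, ci, drop = FALSE]
}

#' Resize an image/mask pair
#'
#' The image is resampled with bilinear interpolation; the mask with
#' nearest-neighbor, so it stays strictly binary.
#'
#' @param image numeric matrix
#' @param mask binary matrix of the same shape
#' @param target_size positive integer side length of the (square) output
#' @return list with `image` and `mask` matrices of the target size
#' @export
resize_pair <- function(image, mask, target_size = 256L) {
  target_size <- as.integer(target_size)
  if (target_size <= 0) stop("target_size must be positive")
  if (!all(dim(image) == dim(mask))) stop("image/mask shape mismatch")
  list(image = bilinear_resize(image, c(target_size, target_size)),
       mask = nearest_resize(mask, c(target_size, target_size)))
}

#' Build a training sample
#'
#' @param image matrix in `[0, 1]`
#' @param mask binary matrix, same shape
#' @param flipped whether this sample is a horizontal mirror of an original
#' @export
training_sample <- function(image, mask, flipped = FALSE) {
  if (!all(dim(image) == dim(mask))) stop("image/mask shape mismatch")
  if (min(image) < 0 || max(image) > 1)
    stop("training image values must lie in [0, 1]")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  structure(list(image = image, mask = mask, flipped = isTRUE(flipped)),
            class = "training_sample")
}

hflip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Double a training set by horizontal flipping
#'
#' Returns the originals followed by their horizontal mirrors (image and
#' mask flipped about the vertical axis, `flipped = TRUE`), a deterministic
#' dataset expansion.
#'
#' @param samples list of [training_sample()]s
#' @return list of length `2 * length(samples)`
#' @export
flip_double <- function(samples) {
  flips <- lapply(samples, function(s)
    training_sample(hflip(s$image), hflip(s$mask), flipped = TRUE))
  c(samples, flips)
}

#' Preprocess a phantom sample (or CT slice + mask) for training
#'
#' Applies windowing/normalization and, when needed, resizing to the
#' target side length.
#'
#' @param sample a `phantom_sample`, or a list with `image` (HU) and `mask`
#' @param w a [window_setting()]
#' @param target_size output side length (default: keep input size)
#' @export
prepare_sample <- function(sample, w = window_setting(), target_size = NULL) {
  img <- window_and_normalize(sample$image, w)
  msk <- sample$mask
  if (!is.null(target_size) && target_size != nrow(img)) {
    rp <- resize_pair(img, msk, target_size)
    img <- rp$image; msk <- rp$mask
  }
  training_sample(img, msk)
}
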