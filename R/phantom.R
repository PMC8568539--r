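#' Phantom specification for synthetic abdominal CT slices
#'
#' Describes the geometry and attenuation of a simple abdominal phantom:
#' an elliptical soft-tissue body on an air background, a bright spine on
#' the vertical midline, and two ellipsoidal kidneys placed symmetrically
#' left and right of the spine, optionally containing low-attenuation
#' cysts. All attenuations are in Hounsfield units (HU); air outside the
#' body is fixed at -1000 HU. Kidney size is given as ellipsoid semiaxes
#' (a, b, c) in mm: a across the image (x), b down the image (y), c along
#' the slice axis (z).
#'
#' @param image_size pixels per side (square slices)
#' @param pixel_spacing_mm in-plane pixel spacing, mm
#' @param slice_thickness_mm nominal slice thickness, mm (metadata only;
#'   volumetry integrates over `inter_slice_mm`)
#' @param inter_slice_mm distance between consecutive slices, mm
#' @param body_hu,spine_hu,kidney_hu,cyst_hu region attenuations, HU
#' @param noise_sd_hu standard deviation of additive Gaussian noise, HU
#' @param n_cysts_per_kidney number of cysts placed inside each kidney
#' @param kidney_semiaxes_mm numeric triple (a, b, c), mm
#' @param kidney_offset_frac kidney center offset from the spine column,
#'   as a fraction of image width
#' @param jitter_frac maximal seeded jitter of kidney centers, as a
#'   fraction of image size (0 gives exactly symmetric placement)
#' @param seed integer seed making every generated sample reproducible
#' @return an object of class `phantom_spec`
#' @export
phantom_spec <- function(image_size = 256L,
                         pixel_spacing_mm = 0.625,
                         slice_thickness_mm = 1.0,
                         inter_slice_mm = 0.5,
                         body_hu = 40,
                         spine_hu = 700,
                         kidney_hu = 30,
                         cyst_hu = 10,
                         noise_sd_hu = 12,
                         n_cysts_per_kidney = 0L,
                         kidney_semiaxes_mm = c(20, 15, 30),
                         kidney_offset_frac = 0.28,
                         jitter_frac = 0.01,
                         seed = 1L) {
  spec <- structure(list(
    image_size = as.integer(image_size),
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm,
    inter_slice_mm = inter_slice_mm,
    body_hu = body_hu, spine_hu = spine_hu,
    kidney_hu = kidney_hu, cyst_hu = cyst_hu,
    noise_sd_hu = noise_sd_hu,
    n_cysts_per_kidney = as.integer(n_cysts_per_kidney),
    kidney_semiaxes_mm = as.numeric(kidney_semiaxes_mm),
    kidney_offset_frac = kidney_offset_frac,
    jitter_frac = jitter_frac,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with(spec, {
    if (image_size < 16) stop("image_size must be at least 16 pixels")
    if (pixel_spacing_mm <= 0 || slice_thickness_mm <= 0 || inter_slice_mm <= 0)
      stop("all spacings must be strictly positive")
    if (noise_sd_hu < 0) stop("noise_sd_hu must be non-negative")
    if (n_cysts_per_kidney < 0) stop("n_cysts_per_kidney must be non-negative")
    if (length(kidney_semiaxes_mm) != 3 || any(kidney_semiaxes_mm <= 0))
      stop("kidney_semiaxes_mm must be three strictly positive values")
    if (kidney_offset_frac <= 0 || kidney_offset_frac >= 0.5)
      stop("kidney_offset_frac must lie in (0, 0.5)")
    hus <- c(-1000, body_hu, spine_hu, kidney_hu, cyst_hu)
    if (anyDuplicated(hus))
      stop("region HU values collide; body/spine/kidney/cyst/air must differ")
  })
  geom <- phantom_geometry(spec, jitter = matrix(0, 2, 2))
  check_kidney_placement(spec, geom)
  invisible(spec)
}

# Fixed scene geometry in pixel coordinates (rows = y, cols = x, 1-based).
phantom_geometry <- function(spec, jitter) {
  n <- spec$image_size
  cr <- (n + 1) / 2
  spine_col <- n %/% 2L + 1L
  ax <- spec$kidney_semiaxes_mm[1] / spec$pixel_spacing_mm
  by <- spec$kidney_semiaxes_mm[2] / spec$pixel_spacing_mm
  off <- spec$kidney_offset_frac * n
  list(
    body_c = c(cr, cr), body_r = c(0.38 * n, 0.45 * n),      # (row, col) semiaxes
    spine_c = c(cr, spine_col), spine_r = c(0.055 * n, 0.04 * n),
    spine_col = spine_col,
    kidney_ax = ax, kidney_by = by,
    # row 1: anatomical-right kidney (image left); row 2: anatomical-left
    kidney_c = rbind(c(cr, spine_col - off) + jitter[1, ],
                     c(cr, spine_col + off) + jitter[2, ]))
}

check_kidney_placement <- function(spec, geom) {
  th <- seq(0, 2 * pi, length.out = 97L)
  for (k in 1:2) {
    kc <- geom$kidney_c[k, ]
    br <- kc[1] + geom$kidney_by * sin(th)
    bc <- kc[2] + geom$kidney_ax * cos(th)
    inside_body <- ((br - geom$body_c[1]) / geom$body_r[1])^2 +
      ((bc - geom$body_c[2]) / geom$body_r[2])^2
    if (any(inside_body > 1))
      stop("kidney ellipse exits the body outline; shrink kidneys or offset")
    in_spine <- ((br - geom$spine_c[1]) / geom$spine_r[1])^2 +
      ((bc - geom$spine_c[2]) / geom$spine_r[2])^2
    if (any(in_spine <= 1) ||
        (k == 1 && max(bc) >= geom$spine_col) ||
        (k == 2 && min(bc) <= geom$spine_col))
      stop("kidney ellipse overlaps the spine / crosses the dividing line")
  }
  invisible(TRUE)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ellipse_mask <- function(n, center, semi_row, semi_col) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  ((rows - center[1]) / semi_row)^2 + ((cols - center[2]) / semi_col)^2 <= 1
}

# Sample cyst centers/radii inside the sphere inscribed in the kidney
# ellipsoid (guarantees cysts never cross the kidney boundary). Units:
# dimensionless fractions of the inscribed radius.
sample_cysts <- function(n_cysts) {
  if (n_cysts == 0)
    return(list(r = numeric(0), u = numeric(0), v = numeric(0), wz = numeric(0)))
  r <- runif(n_cysts, 0.15, 0.35)
  # direction on the sphere x radial factor, scaled so ball stays inside
  z <- runif(n_cysts, -1, 1)
  t <- runif(n_cysts, 0, 2 * pi)
  s <- runif(n_cysts)^(1 / 3) * (1 - r)
  list(r = r,
       u = s * sqrt(1 - z^2) * cos(t),
       v = s * sqrt(1 - z^2) * sin(t),
       wz = s * z)
}

#' Generate one synthetic abdominal CT slice with ground truth
#'
#' Draws the central (z = 0) section of the phantom: body ellipse, spine,
#' two kidney ellipses with optional cysts, plus i.i.d. Gaussian noise.
#' The binary mask marks all kidney pixels; cysts count as kidney. The
#' side-label map distinguishes the anatomical-left kidney (displayed on
#' the image right under the radiological convention) from the
#' anatomical-right kidney.
#'
#' @param spec a [phantom_spec()]
#' @param slice_seed optional seed overriding `spec$seed`
#' @return a `phantom_sample`: list with `image` (HU matrix), `mask`
#'   (0/1 matrix), `side_labels` (0 background, 1 anatomical-left,
#'   2 anatomical-right), `spine_column`, and the generating `spec`
#' @export
generate_slice <- function(spec, slice_seed = spec$seed) {
  validate_phantom_spec(spec)
  with_seed(slice_seed, {
    n <- spec$image_size
    jit <- matrix(runif(4, -1, 1) * spec$jitter_frac * n, 2, 2)
    geom <- phantom_geometry(spec, jit)
    check_kidney_placement(spec, geom)
    cysts <- lapply(1:2, function(k) sample_cysts(spec$n_cysts_per_kidney))
    out <- render_slice(spec, geom, cysts, z_mm = 0)
    out$image <- out$image +
      matrix(rnorm(n * n, 0, spec$noise_sd_hu), n, n)
    structure(c(out, list(spec = spec)), class = "phantom_sample")
  })
}

# Deterministic rendering of one z-section given fixed geometry and cysts.
render_slice <- function(spec, geom, cysts, z_mm) {
  n <- spec$image_size
  img <- matrix(-1000, n, n)
  img[ellipse_mask(n, geom$body_c, geom$body_r[1], geom$body_r[2])] <- spec$body_hu
  side <- matrix(0L, n, n)
  a <- spec$kidney_semiaxes_mm[1]
  b <- spec$kidney_semiaxes_mm[2]
  cc <- spec$kidney_semiaxes_mm[3]
  rins <- min(a, b, cc)                      # inscribed-sphere radius, mm
  scale2 <- 1 - (z_mm / cc)^2
  for (k in 1:2) {
    if (scale2 <= 0) next
    axz <- geom$kidney_ax * sqrt(scale2)
    byz <- geom$kidney_by * sqrt(scale2)
    km <- ellipse_mask(n, geom$kidney_c[k, ], byz, axz)
    img[km] <- spec$kidney_hu
    side[km] <- if (k == 1) 2L else 1L       # image-left = anatomical right
    cy <- cysts[[k]]
    for (i in seq_along(cy$r)) {
      r_mm <- cy$r[i] * rins
      ctr_row <- geom$kidney_c[k, 1] + cy$v[i] * rins / spec$pixel_spacing_mm
      ctr_col <- geom$kidney_c[k, 2] + cy$u[i] * rins / spec$pixel_spacing_mm
      dz <- z_mm - cy$wz[i] * rins
      if (abs(dz) >= r_mm) next
      r_px <- sqrt(r_mm^2 - dz^2) / spec$pixel_spacing_mm
      dm <- ellipse_mask(n, c(ctr_row, ctr_col), r_px, r_px)
      img[dm] <- spec$cyst_hu
    }
  }
  img[ellipse_mask(n, geom$spine_c, geom$spine_r[1], geom$spine_r[2])] <- spec$spine_hu
  list(image = img, mask = (side > 0) + 0L, side_labels = side,
       spine_column = geom$spine_col)
}

#' Generate a coherent series of phantom slices through 3-D kidneys
#'
#' Slices are parallel sections of two fixed kidney ellipsoids with
#' semiaxes `kidney_semiaxes_mm`, taken at z-positions spaced by
#' `inter_slice_mm` and centered on the kidney midplane. The body and
#' spine are constant across slices (cylinders); cysts are 3-D balls
#' inside each kidney, so their cross-sections are coherent across
#' slices too.
#'
#' @param spec a [phantom_spec()]
#' @param n_slices number of slices (>= 1)
#' @return a `phantom_series`: list with `slices` (list of
#'   `phantom_sample`), `z_mm` (per-slice positions) and `spec`
#' @export
generate_series <- function(spec, n_slices) {
  validate_phantom_spec(spec)
  n_slices <- as.integer(n_slices)
  if (n_slices < 1) stop("n_slices must be >= 1")
  with_seed(spec$seed, {
    n <- spec$image_size
    jit <- matrix(runif(4, -1, 1) * spec$jitter_frac * n, 2, 2)
    geom <- phantom_geometry(spec, jit)
    check_kidney_placement(spec, geom)
    cysts <- lapply(1:2, function(k) sample_cysts(spec$n_cysts_per_kidney))
    z <- (seq_len(n_slices) - (n_slices + 1) / 2) * spec$inter_slice_mm
    slices <- lapply(z, function(zi) {
      out <- render_slice(spec, geom, cysts, z_mm = zi)
      out$image <- out$image + matrix(rnorm(n * n, 0, spec$noise_sd_hu), n, n)
      structure(c(out, list(spec = spec, z_mm = zi)), class = "phantom_sample")
    })
    structure(list(slices = slices, z_mm = z, spec = spec),
              class = "phantom_series")
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: %dx%d px @ %.3f mm, kidneys (a,b,c) = (%g, %g, %g) mm,\n",
    x$image_size, x$image_size, x$pixel_spacing_mm,
    x$kidney_semiaxes_mm[1], x$kidney_semiaxes_mm[2], x$kidney_semiaxes_mm[3]))
  cat(sprintf("  HU body/spine/kidney/cyst = %g/%g/%g/%g, noise sd %g HU, %d cyst(s)/kidney, seed %d\n",
              x$body_hu, x$spine_hu, x$kidney_hu, x$cyst_hu,
              x$noise_sd_hu, x$n_cysts_per_kidney, x$seed))
  invisible(x)
}
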