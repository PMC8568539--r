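test_that("soft-tissue window 420/60 maps HU to [0,1] as specified", {
  w <- window_setting(420, 60)
  expect_equal(window_and_normalize(matrix(-150), w)[1, 1], 0)
  expect_equal(window_and_normalize(matrix(270), w)[1, 1], 1)
  expect_equal(window_and_normalize(matrix(60), w)[1, 1], 0.5)
  expect_equal(window_and_normalize(matrix(-1000), w)[1, 1], 0)
  # monotone non-decreasing in HU
  hu <- matrix(sort(runif(200, -1200, 1200)), 1)
  expect_true(all(diff(as.vector(window_and_normalize(hu, w))) >= 0))
  # idempotent after mapping back into the window range
  y <- window_and_normalize(hu, w)
  back <- y * w$width_hu + (w$center_hu - w$width_hu / 2)
  expect_equal(window_and_normalize(back, w), y)
  expect_error(window_setting(width_hu = 0), "positive")
})

test_that("resize_pair interpolates the image and keeps the mask binary", {
  img <- matrix(3.7, 512, 512)
  msk <- matrix(1L, 512, 512)
  rp <- resize_pair(img, msk, 256)
  expect_equal(dim(rp$image), c(256, 256))
  expect_true(all(rp$image == 3.7))
  expect_true(all(rp$mask == 1))
  # centered disk of radius 100 px at 512 -> area ~ pi * 50^2 at 256
  rows <- matrix(seq_len(512), 512, 512)
  cols <- t(rows)
  disk <- ((rows - 256.5)^2 + (cols - 256.5)^2 <= 100^2) + 0L
  rp <- resize_pair(matrix(0, 512, 512), disk, 256)
  expect_true(all(rp$mask %in% c(0L, 1L)))
  expect_lt(abs(sum(rp$mask) - pi * 50^2) / (pi * 50^2), 0.05)
  expect_error(resize_pair(img, msk, 0), "positive")
})

test_that("flip doubling doubles, mirrors, and is an involution", {
  set.seed(3)
  samples <- lapply(1:52, function(i) {
    m <- matrix(0L, 16, 16)
    m[5:9, 2:6] <- 1L                 # kidney only in the left half
    training_sample(matrix(runif(256), 16), m)
  })
  doubled <- flip_double(samples)
  expect_length(doubled, 104)
  expect_false(any(vapply(doubled[1:52], `[[`, TRUE, "flipped")))
  expect_true(all(vapply(doubled[53:104], `[[`, TRUE, "flipped")))
  # mask pixel counts preserved, kidney moved to the right half
  expect_identical(sum(doubled[[53]]$mask), sum(samples[[1]]$mask))
  expect_true(all(which(doubled[[53]]$mask == 1, arr.ind = TRUE)[, 2] > 8))
  # flip of a flip restores the original bit-exactly
  redoubled <- flip_double(doubled[53:104])
  expect_identical(redoubled[[53]]$image, samples[[1]]$image)
  expect_identical(redoubled[[53]]$mask, samples[[1]]$mask)
})

test_that("DICOM round-trip preserves HU, spacing and geometry", {
  dir <- withr::local_tempdir()
  set.seed(11)
  hu <- matrix(sample(-1000:2000, 32 * 32), 32, 32)
  sl <- ct_slice(hu, pixel_spacing_mm = c(0.625, 0.625),
                 slice_thickness_mm = 1.0, z_position_mm = 5.0)
  write_dicom(sl, file.path(dir, "a.dcm"))
  rd <- read_dicom(file.path(dir, "a.dcm"))
  expect_equal(rd$pixels, hu, ignore_attr = TRUE)
  expect_equal(rd$pixel_spacing_mm, c(0.625, 0.625))
  expect_equal(rd$slice_thickness_mm, 1.0)
  expect_equal(rd$z_position_mm, 5.0)
})

test_that("DICOM series are ordered by z and mixed series rejected", {
  dir <- withr::local_tempdir()
  for (z in c(5, 4)) {
    sl <- ct_slice(matrix(z, 8, 8), c(0.625, 0.625), 1.0, z_position_mm = z)
    write_dicom(sl, file.path(dir, sprintf("z%d.dcm", z)))
  }
  series <- read_dicom_series(dir)
  expect_equal(vapply(series, function(s) s$z_position_mm, 0), c(4, 5))
  expect_true(all(series[[1]]$pixels == 4))
  write_dicom(ct_slice(matrix(0, 4, 4), c(1, 1)), file.path(dir, "odd.dcm"))
  expect_error(read_dicom_series(dir), "mixed")
})

test_that("missing rescale tags are reported by tag name", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "norescale.dcm")
  con <- file(path, "wb")
  writeBin(raw(128), con); writeChar("DICM", con, nchars = 4, eos = NULL)
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  rdaunet:::dcm_write_element(con, 0x0028, 0x0010, "US", us(2))
  rdaunet:::dcm_write_element(con, 0x0028, 0x0011, "US", us(2))
  rdaunet:::dcm_write_element(con, 0x0028, 0x0030, "DS", charToRaw("1\\1 "))
  rdaunet:::dcm_write_element(con, 0x7FE0, 0x0010, "OW", raw(8))
  close(con)
  expect_error(read_dicom(path), "0028,105")  # names the missing rescale tag
})

test_that("NIfTI round-trip preserves data and spacing", {
  dir <- withr::local_tempdir()
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  f <- file.path(dir, "x.nii")
  write_nifti(arr, f, pixdim = c(0.625, 0.625, 1.0), datatype = 64L)
  nf <- read_nifti(f)
  expect_equal(nf$data, arr)
  expect_equal(nf$pixdim, c(0.625, 0.625, 1.0))
  # int16 labels round-trip exactly
  lab <- array(sample(0:2, 60, replace = TRUE), c(6, 5, 2))
  write_nifti(lab, f, pixdim = c(1, 1, 2), datatype = 4L)
  expect_identical(read_nifti(f)$data, lab)
})

test_that("NIfTI output is readable by an independent implementation", {
  # nibabel (Python, pre-installed) acts as the external oracle
  dir <- withr::local_tempdir()
  arr <- array(seq_len(24) * 0.5, c(4, 3, 2))
  f <- file.path(dir, "oracle.nii")
  write_nifti(arr, f, pixdim = c(0.625, 0.625, 1.0), datatype = 16L)
  script <- sprintf(
    "import nibabel, json; im = nibabel.load('%s'); print(json.dumps({'zooms': [float(z) for z in im.header.get_zooms()], 'sum': float(im.get_fdata().sum()), 'shape': list(im.shape)}))", f)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = FALSE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(res$zooms, c(0.625, 0.625, 1.0), tolerance = 1e-6)
  expect_equal(res$shape, c(4, 3, 2))
  expect_equal(res$sum, sum(arr), tolerance = 1e-6)
})

test_that("prepare_sample windows, normalizes and resizes phantoms", {
  sl <- generate_slice(tiny_spec(seed = 2))
  ts <- prepare_sample(sl, target_size = 32)
  expect_equal(dim(ts$image), c(32, 32))
  expect_true(min(ts$image) >= 0 && max(ts$image) <= 1)
  expect_true(all(ts$mask %in% c(0L, 1L)))
})
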