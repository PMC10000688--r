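smooth_image <- function(h, w) {
  x <- outer(seq_len(h), seq_len(w),
             function(i, j) 150 + 70 * sin(i / 23) * cos(j / 31))
  array(round(c(x, x * 0.8, x * 0.6)), c(h, w, 3))
}

test_that("pyramid levels halve until they fit one tile", {
  img <- smooth_image(1024, 1024)
  f <- tempfile(fileext = ".tif")
  pyr <- write_pyramid(img, f, compression = "none",
                       microns_per_pixel = 0.467, magnification = "200x")
  expect_equal(sapply(pyr$levels, `[[`, "width"), c(1024, 512, 256))
  expect_equal(sapply(pyr$levels, `[[`, "height"), c(1024, 512, 256))
  expect_equal(sapply(pyr$levels, `[[`, "downsample"), c(1, 2, 4))

  # every reduced-level pixel is the mean of its 2x2 parent block (+/- 1)
  for (li in 2:3) {
    lvl <- read_region(pyr, li, 0, 0, 1024 / 2^(li - 1), 1024 / 2^(li - 1))
    parent <- read_region(pyr, li - 1, 0, 0, 1024 / 2^(li - 2), 1024 / 2^(li - 2))
    expect_lte(max(abs(lvl - pool2(parent))), 1)
  }
})

test_that("lossless round trip is bit-exact and supports region reads", {
  set.seed(2)
  img <- array(sample(0:255, 300 * 520 * 3, TRUE), c(300, 520, 3))
  f <- tempfile(fileext = ".tif")
  pyr <- write_pyramid(img, f, compression = "none", microns_per_pixel = 0.467)
  expect_identical(read_region(pyr, 1, 0, 0, 520, 300), img + 0)

  # 1x1 read
  expect_equal(dim(read_region(pyr, 1, 17, 23, 1, 1)), c(1, 1, 3))
  expect_equal(as.vector(read_region(pyr, 1, 17, 23, 1, 1)),
               as.vector(img[24, 18, ]))

  # a region spanning 4 tiles equals stitching 4 single-tile reads
  reg <- read_region(pyr, 1, 200, 200, 112, 80)
  stitched <- array(0, c(80, 112, 3))
  stitched[1:56, 1:56, ]   <- read_region(pyr, 1, 200, 200, 56, 56)
  stitched[1:56, 57:112, ] <- read_region(pyr, 1, 256, 200, 56, 56)
  stitched[57:80, 1:56, ]  <- read_region(pyr, 1, 200, 256, 56, 24)
  stitched[57:80, 57:112, ] <- read_region(pyr, 1, 256, 256, 56, 24)
  expect_identical(reg, stitched)

  # bounds violations raise range errors
  expect_error(read_region(pyr, 1, 510, 0, 20, 20), class = "sn_range_error")
  expect_error(read_region(pyr, 5, 0, 0, 1, 1), class = "sn_range_error")
  expect_error(read_region(pyr, 1, 0, 0, 0, 1), class = "sn_range_error")
})

test_that("JPEG tiles honor the quality-80 error budget", {
  # phantom content is the hard case: sharp chroma edges at nuclei;
  # planar (per-channel) encoding keeps full chroma resolution
  img <- small_phantom(seed = 2)$image
  f <- tempfile(fileext = ".tif")
  pyr <- write_pyramid(img, f, compression = "jpeg", jpeg_quality = 80,
                       microns_per_pixel = 0.467)
  back <- read_region(pyr, 1, 0, 0, dim(img)[2], dim(img)[1])
  expect_lte(mean(abs(back - img)), 3)
  expect_identical(pyr$compression, "jpeg")
  expect_identical(pyr$jpeg_quality, 80L)
  # smooth content compresses much harder
  img2 <- smooth_image(400, 300)
  f2 <- tempfile(fileext = ".tif")
  pyr2 <- write_pyramid(img2, f2, compression = "jpeg", jpeg_quality = 80,
                        microns_per_pixel = 0.467)
  expect_lte(mean(abs(read_region(pyr2, 1, 0, 0, 300, 400) - img2)), 1)
})

test_that("resolution metadata survives the round trip exactly", {
  img <- smooth_image(128, 128)
  f <- tempfile(fileext = ".tif")
  pyr <- write_pyramid(img, f, tile_size = 64, compression = "none",
                       microns_per_pixel = 0.233, magnification = "400x")
  expect_identical(pyr$microns_per_pixel, 0.233)
  expect_identical(pyr$tile_size, 64)
  expect_identical(pyr$magnification_label, "400x")
  reopened <- open_pyramid(f)
  expect_identical(reopened$microns_per_pixel, 0.233)
  expect_identical(reopened$tile_size, 64)
})

test_that("written files parse with an independent TIFF reader", {
  skip_if_not_installed("tiff")
  set.seed(4)
  img <- array(sample(0:255, 200 * 200 * 3, TRUE), c(200, 200, 3))
  f <- tempfile(fileext = ".tif")
  write_pyramid(img, f, tile_size = 128, compression = "none",
                microns_per_pixel = 0.467)
  pages <- suppressWarnings(tiff::readTIFF(f, all = TRUE, info = TRUE))
  expect_length(pages, 2)                       # 200 -> 100
  expect_equal(round(pages[[1]] * 255), img + 0, ignore_attr = TRUE)
  # libtiff reports pixels-per-cm; 0.467 um/px = 10000/0.467 px/cm
  xres <- attr(pages[[1]], "x.resolution")
  expect_equal(1e4 / xres, 0.467, tolerance = 1e-6)
  expect_identical(attr(pages[[1]], "resolution.unit"), "cm")

  # JPEG variant decodes identically through libtiff's codec path
  fj <- tempfile(fileext = ".tif")
  pyrj <- write_pyramid(smooth_image(200, 200), fj, tile_size = 128,
                        compression = "jpeg", microns_per_pixel = 0.467)
  native <- suppressWarnings(tiff::readTIFF(fj, native = TRUE))
  v <- as.vector(unclass(native))
  lib <- array(c(matrix(bitwAnd(v, 255), 200, 200, byrow = TRUE),
                 matrix(bitwAnd(bitwShiftR(v, 8), 255), 200, 200, byrow = TRUE),
                 matrix(bitwAnd(bitwShiftR(v, 16), 255), 200, 200, byrow = TRUE)),
               c(200, 200, 3))
  ours <- read_region(pyrj, 1, 0, 0, 200, 200)
  expect_lte(mean(abs(lib - ours)), 1)
})

test_that("odd dimensions pool and tile correctly", {
  img <- smooth_image(129, 257)
  expect_equal(dim(pool2(img)), c(65, 129, 3))
  # the documented 2x2 block mean
  blk <- array(c(10, 30, 20, 40), c(2, 2, 1))[, , c(1, 1, 1)]
  expect_equal(as.vector(pool2(blk)), c(25, 25, 25))
  f <- tempfile(fileext = ".tif")
  pyr <- write_pyramid(img, f, tile_size = 64, compression = "none",
                       microns_per_pixel = 0.467)
  expect_identical(read_region(pyr, 1, 0, 0, 257, 129), img + 0)
  expect_equal(sapply(pyr$levels, `[[`, "width"), c(257, 129, 65, 33))
})

test_that("400x input resamples to 200x-equivalent, 200x passes through", {
  img <- smooth_image(128, 128)
  rs <- resample_to_200x(img, 0.233)
  expect_equal(rs$microns_per_pixel, 0.466)
  expect_equal(dim(rs$image), c(64, 64, 3))
  expect_equal(rs$image, pool2(img))
  rs2 <- resample_to_200x(img, 0.467)
  expect_identical(rs2$image, img)
  expect_identical(rs2$microns_per_pixel, 0.467)
  expect_error(resample_to_200x(img, NA), class = "sn_metadata_error")
  expect_error(resample_to_200x(img), class = "sn_metadata_error")
})
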