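test_that("PNG round trip preserves values within 8-bit quantization", {
  img <- withr::with_seed(11, RasterImage(array(runif(8 * 6 * 3),
                                                c(8, 6, 3)), "srgb"))
  p <- withr::local_tempfile(fileext = ".png")
  writeRaster(img, p)
  back <- readRaster(p)
  expect_identical(dim(back), c(8L, 6L, 3L))
  expect_identical(colorSpace(back), "srgb")
  expect_lt(max(abs(values(back) - values(img))), 1 / 255)
})

test_that("TIFF and JPEG formats are read and written", {
  img <- withr::with_seed(12, RasterImage(matrix(runif(64), 8, 8), "srgb"))
  pt <- withr::local_tempfile(fileext = ".tiff")
  writeRaster(img, pt)
  expect_lt(max(abs(values(readRaster(pt)) - values(img))), 1 / 255)
  pj <- withr::local_tempfile(fileext = ".jpg")
  writeRaster(img, pj)
  expect_lt(max(abs(values(readRaster(pj)) - values(img))), 0.15)  # lossy
})

test_that("saturated 2x2 grayscale file decodes to ones with k = 1", {
  p <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 2, 2), p)
  img <- readRaster(p)
  expect_identical(dim(img), c(2L, 2L, 1L))
  expect_true(all(values(img) == 1))
})

test_that("unreadable paths and unsupported formats raise errors", {
  expect_error(readRaster("no/such/file.png"), "no such file")
  p <- withr::local_tempfile(fileext = ".bmp")
  writeLines("x", p)
  expect_error(readRaster(p), "unsupported image format")
})

test_that("sRGB primaries convert to their reference CIELab coordinates", {
  arr <- array(0, c(3, 1, 3))
  arr[1, 1, ] <- c(1, 1, 1)       # white
  arr[2, 1, ] <- c(0, 0, 0)       # black
  arr[3, 1, ] <- c(0.5, 0.5, 0.5) # mid-gray
  lab <- values(toCielab(RasterImage(arr, "srgb")))
  expect_equal(lab[1, 1, ], c(100, 0, 0), tolerance = 1e-3)
  expect_equal(lab[2, 1, ], c(0, 0, 0), tolerance = 1e-6)
  ref <- refSrgbToLab(c(0.5, 0.5, 0.5))
  expect_equal(lab[3, 1, ], unname(ref), tolerance = 0.05)
  expect_lt(abs(lab[3, 1, 2]), 1e-3)   # a ~ 0 for gray
  expect_lt(abs(lab[3, 1, 3]), 1e-3)   # b ~ 0
})

test_that("random sRGB colors match the reference conversion formulas", {
  cols <- withr::with_seed(4, matrix(runif(30), ncol = 3))
  arr <- array(cols, c(10, 1, 3))
  lab <- values(toCielab(RasterImage(arr, "srgb")))
  for (i in 1:10) {
    ref <- refSrgbToLab(cols[i, ])
    expect_equal(unname(lab[i, 1, ]), unname(ref), tolerance = 0.05)
  }
})

test_that("grayscale images lift to luminance-only CIELab", {
  img <- RasterImage(matrix(c(0, 0.25, 0.5, 1), 2, 2), "srgb")
  lab <- toCielab(img)
  expect_identical(nChannels(lab), 3L)
  expect_equal(values(lab)[, , 1], matrix(c(0, 25, 50, 100), 2, 2))
  expect_true(all(values(lab)[, , 2:3] == 0))
})

test_that("CIELab -> sRGB -> CIELab round trip is tight for in-gamut colors", {
  img <- withr::with_seed(9, RasterImage(array(runif(5 * 5 * 3),
                                               c(5, 5, 3)), "srgb"))
  lab <- toCielab(img)
  back <- values(labToSrgb(lab))
  expect_lt(max(abs(back - values(img))), 1e-3)
})

test_that("converting an already-CIELab image warns and is a no-op", {
  img <- RasterImage(array(50, c(2, 2, 3)), "cielab")
  expect_warning(out <- toCielab(img), "already")
  expect_identical(values(out), values(img))
})

test_that("unit normalization applies the fixed nominal CIELab ranges", {
  arr <- array(0, c(2, 1, 3))
  arr[1, 1, ] <- c(100, 0, 0)
  arr[2, 1, ] <- c(0, -128, -128)
  u <- normalizeUnit(RasterImage(arr, "cielab"))
  expect_identical(colorSpace(u), "unit")
  expect_equal(values(u)[1, 1, ], c(1, 128 / 255, 128 / 255),
               tolerance = 1e-12)
  expect_equal(values(u)[2, 1, ], c(0, 0, 0), tolerance = 1e-12)
  # arbitrary triple against the affine map computed directly
  arr2 <- array(c(37.5, 12, -41), c(1, 1, 3))
  u2 <- values(normalizeUnit(RasterImage(arr2, "cielab")))
  expect_equal(as.vector(u2),
               c(37.5 / 100, (12 + 128) / 255, (-41 + 128) / 255))
})

test_that("unit normalization is idempotent and keeps sRGB untouched", {
  img <- withr::with_seed(2, RasterImage(array(runif(12), c(2, 2, 3)),
                                         "srgb"))
  u1 <- normalizeUnit(img)
  expect_equal(values(u1), values(img))
  expect_identical(values(normalizeUnit(u1)), values(u1))
})

test_that("RasterImage validity rejects bad channel counts and ranges", {
  expect_error(RasterImage(array(0, c(2, 2, 2)), "srgb"), "1 or 3")
  expect_error(RasterImage(array(2, c(2, 2, 3)), "srgb"), "\\[0,1\\]")
  expect_error(RasterImage(array(150, c(2, 2, 3)), "cielab"), "L channel")
  expect_error(RasterImage(array(NA_real_, c(2, 2, 1)), "srgb"), "finite")
})

test_that("trace image sequences are written as zero-padded PNGs", {
  img <- RasterImage(matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4), "srgb")
  tr <- runSfcm(img, smoothingConfig(r = 2, alpha = 1, seed = 3))
  d <- withr::local_tempdir()
  paths <- writeTraceImages(tr, d)
  expect_true(all(file.exists(paths)))
  expect_match(basename(paths)[1], "^iter_0000\\.png$")
})
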