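test_that("BSQ write/read round trip preserves data, wavelengths and depth", {
  set.seed(101)
  d <- array(sample.int(4096L, 4L * 16L * 12L, replace = TRUE) - 1L,
             c(4L, 16L, 12L))
  cube <- HyperCube(d, c(550, 600, 700, 900), 12L)
  path <- file.path(tempdir(), "rt.bsq")
  writeBSQ(cube, path)
  back <- readBSQ(path)
  expect_identical(dim(back@data), dim(cube@data))
  expect_equal(back@data, cube@data)
  expect_equal(back@wavelengths, cube@wavelengths)
  expect_equal(back@bitDepth, cube@bitDepth)
})

test_that("8-bit cubes round trip through single-byte storage", {
  d <- array(sample.int(256L, 2L * 8L * 8L, replace = TRUE) - 1L,
             c(2L, 8L, 8L))
  cube <- HyperCube(d, c(550, 600), 8L)
  path <- file.path(tempdir(), "rt8.bsq")
  writeBSQ(cube, path)
  expect_equal(file.size(path), 2 * 8 * 8)
  expect_equal(readBSQ(path)@data, cube@data)
})

test_that("values above the signed 16-bit range survive the round trip", {
  d <- array(c(65535, 40000, 32768, 0, 1, 12345, 65000, 7),
             c(2L, 2L, 2L))
  cube <- HyperCube(d, c(550, 600), 16L)
  path <- file.path(tempdir(), "rt16.bsq")
  writeBSQ(cube, path)
  expect_equal(readBSQ(path)@data, d)
})

test_that("ENVI headers with a wavelength range expand to a linear grid", {
  path <- file.path(tempdir(), "range.bsq")
  d <- array(0:23, c(4L, 3L, 2L))
  writeBSQ(HyperCube(d, seq(550, 1000, length.out = 4L), 12L), path)
  back <- readBSQ(path)
  expect_equal(back@wavelengths, seq(550, 1000, length.out = 4L))
})

test_that("malformed inputs are rejected with clear errors", {
  expect_error(readBSQ(file.path(tempdir(), "missing.bsq")))
  hdr <- file.path(tempdir(), "bad.bsq.hdr")
  bin <- file.path(tempdir(), "bad.bsq")
  writeLines(c("ENVI", "samples = 4", "lines = 4", "bands = 2",
               "data type = 12", "interleave = bil", "bit depth = 12",
               "wavelength = {550, 600}"), hdr)
  writeBin(raw(64), bin)
  expect_error(readBSQ(bin), "interleave")
  # truncated payload
  writeLines(c("ENVI", "samples = 4", "lines = 4", "bands = 2",
               "data type = 12", "interleave = bsq", "bit depth = 12",
               "wavelength = {550, 600}"), hdr)
  writeBin(raw(10), bin)
  expect_error(readBSQ(bin))
})

test_that("non-integer intensities cannot be written as BSQ", {
  cube <- HyperCube(array(c(0.5, 1, 2, 3, 4, 5, 6, 7), c(2L, 2L, 2L)),
                    c(550, 600), 12L)
  expect_error(writeBSQ(cube, file.path(tempdir(), "frac.bsq")),
               "integer")
})

test_that("exportMasks writes one TIFF page per band", {
  m <- array(FALSE, c(3L, 6L, 5L))
  m[1, 1:2, ] <- TRUE
  m[3, , 2] <- TRUE
  stack <- MaskStack(m, "threshold")
  path <- file.path(tempdir(), "masks.tif")
  exportMasks(stack, path)
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_length(pages, 3L)
  expect_equal(dim(pages[[1L]]), c(6L, 5L))
  expect_equal(pages[[1L]] > 0.5, getBand(stack, 1L))
  expect_equal(pages[[3L]] > 0.5, getBand(stack, 3L))
})
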