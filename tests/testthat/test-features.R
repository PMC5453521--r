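test_that("the detector registry lists hessian and accepts new entries", {
  expect_true("hessian" %in% listDetectors())
  dummy <- function(mask, ...) {
    detectFeatures(mask, "hessian")
  }
  registerDetector("dummy-copy", dummy)
  expect_true("dummy-copy" %in% listDetectors())
  expect_error(detectFeatures(matrix(TRUE, 8, 8), "no-such-detector"),
               "unknown detector")
})

test_that("an empty mask warns and yields an empty feature set", {
  expect_warning(fs <- detectFeatures(matrix(FALSE, 20, 20)),
                 "empty foreground")
  expect_equal(length(fs), 0L)
  expect_equal(nrow(featurePoints(fs)), 0L)
})

test_that("features are detected on mask structure with valid geometry", {
  masks <- defaultMasks()
  fs <- detectFeatures(getBand(masks, 1L))
  expect_gt(length(fs), 20L)
  pts <- featurePoints(fs)
  d <- dim(getBand(masks, 1L))
  expect_true(all(pts$row >= 0 & pts$row <= d[1L] - 1))
  expect_true(all(pts$col >= 0 & pts$col <= d[2L] - 1))
  expect_true(all(pts$scale > 0))
  expect_true(all(is.finite(pts$response)))
  desc <- featureDescriptors(fs)
  expect_equal(nrow(desc), length(fs))
  # descriptors are L2-normalized (or zero for flat patches)
  nrm <- sqrt(rowSums(desc^2))
  expect_true(all(abs(nrm - 1) < 1e-6 | nrm < 1e-12))
})

test_that("matching a feature set to itself is the identity pairing", {
  masks <- defaultMasks()
  fs <- detectFeatures(getBand(masks, 1L))
  m <- matchAdjacent(fs, fs, bandA = 1L, bandB = 1L)
  expect_gt(nrow(m@pairs), 0L)
  expect_equal(m@pairs$idxA, m@pairs$idxB)
  # the vectorized distance formula carries ~sqrt(eps) cancellation error,
  # so "zero" self-distances come out near 1e-8, not 1e-16
  expect_true(all(m@pairs$distance < 1e-6))
})

test_that("matches are one-to-one in both directions", {
  masks <- defaultMasks()
  fs1 <- detectFeatures(getBand(masks, 1L))
  fs2 <- detectFeatures(getBand(masks, 2L))
  m <- matchAdjacent(fs1, fs2, bandA = 1L, bandB = 2L)
  expect_false(any(duplicated(m@pairs$idxA)))
  expect_false(any(duplicated(m@pairs$idxB)))
})

test_that("the ratio test removes ambiguous duplicate descriptors", {
  masks <- defaultMasks()
  fs <- detectFeatures(getBand(masks, 1L))
  pts <- featurePoints(fs)
  desc <- featureDescriptors(fs)
  # duplicate every descriptor: each query now has two equally good
  # candidates, so the two-sided ratio test must reject everything
  dup <- new("FeatureSet",
             points = rbind(pts, pts),
             descriptors = rbind(desc, desc),
             detector = "hessian")
  m <- matchAdjacent(fs, dup, bandA = 1L, bandB = 2L)
  expect_equal(nrow(m@pairs), 0L)
})

test_that("a stricter ratio threshold never adds matches", {
  masks <- defaultMasks()
  fs1 <- detectFeatures(getBand(masks, 1L))
  fs2 <- detectFeatures(getBand(masks, 2L))
  loose <- matchAdjacent(fs1, fs2, ratio = 0.9, bandA = 1L, bandB = 2L)
  strict <- matchAdjacent(fs1, fs2, ratio = 0.6, bandA = 1L, bandB = 2L)
  expect_lte(nrow(strict@pairs), nrow(loose@pairs))
  key <- function(m) paste(m@pairs$idxA, m@pairs$idxB)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("exportFeatures writes a readable feature table", {
  masks <- defaultMasks()
  fs <- detectFeatures(getBand(masks, 1L))
  path <- file.path(tempdir(), "features.tsv")
  exportFeatures(fs, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), length(fs))
  expect_true(all(c("row", "col", "scale", "orientation") %in% names(tab)))
})
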