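# tiny handcrafted FeatureSet: identity descriptors so matching is exact
.toyFeatures <- function(coords, descRows) {
  n <- nrow(coords)
  new("FeatureSet",
      points = data.frame(row = coords[, 1L], col = coords[, 2L],
                          scale = rep(2, n), orientation = rep(0, n),
                          response = rep(1, n)),
      descriptors = descRows,
      detector = "toy")
}

.toyMatches <- function(bandA, bandB, idxA, idxB) {
  new("PairMatches", bandA = as.integer(bandA), bandB = as.integer(bandB),
      pairs = data.frame(idxA = as.integer(idxA), idxB = as.integer(idxB),
                         distance = rep(0, length(idxA))))
}

test_that("composeChains follows matches around the loop and closes", {
  # 3 bands, 3 features; feature 3 has no band-2 -> band-3 match
  co <- cbind(c(10, 20, 30), c(10, 20, 30))
  fs <- list(.toyFeatures(co, diag(3)),
             .toyFeatures(co + 1, diag(3)),
             .toyFeatures(co + 2, diag(3)))
  mg <- list(.toyMatches(1, 2, 1:3, 1:3),
             .toyMatches(2, 3, 1:2, 1:2),
             .toyMatches(3, 1, 1:2, 1:2))
  ch <- composeChains(mg, fs)
  expect_equal(nrow(ch@featureIndex), 3L)
  expect_equal(sum(ch@complete), 2L)
  expect_equal(closureDistances(ch)[ch@complete], c(0, 0))
  expect_true(is.na(ch@featureIndex[3L, 3L]))
})

test_that("a loop-closing mismatch shows up as a closure distance", {
  co <- cbind(c(10, 50), c(10, 50))
  fs <- list(.toyFeatures(co, diag(2)),
             .toyFeatures(co, diag(2)),
             .toyFeatures(co, diag(2)))
  mg <- list(.toyMatches(1, 2, 1:2, 1:2),
             .toyMatches(2, 3, 1:2, 1:2),
             .toyMatches(3, 1, 1:2, 2:1))   # swapped return
  ch <- composeChains(mg, fs)
  d <- closureDistances(ch)
  expect_equal(sort(d), rep(sqrt(2) * 40, 2), tolerance = 1e-12)
})

test_that("filterOutliers splits chains by the closure threshold", {
  co <- cbind(c(10, 50), c(10, 50))
  fs <- list(.toyFeatures(co, diag(2)),
             .toyFeatures(co, diag(2)),
             .toyFeatures(co, diag(2)))
  mg <- list(.toyMatches(1, 2, 1:2, 1:2),
             .toyMatches(2, 3, 1:2, 1:2),
             .toyMatches(3, 1, 1:2, 2:1))
  ch <- composeChains(mg, fs)
  fl <- filterOutliers(ch, chainFilterParams(delta = 3))
  expect_equal(fl$stats$raw, 2L)
  expect_equal(fl$stats$retained, 0L)
  fl2 <- filterOutliers(ch, chainFilterParams(delta = 100))
  expect_equal(fl2$stats$retained, 2L)
})

test_that("the cycle residual follows the Eq-type composition exactly", {
  a <- c(0.3, -0.8)
  trs <- list(RigidTransform(a[1]), RigidTransform(a[2]),
              RigidTransform(-sum(a)))
  r <- list(c(0.5, -0.2), c(-0.1, 0.9), c(0.3, 0.3))
  got <- cycleBoundCheck(trs, r)
  Rki <- trs[[3]]@rotation
  Rjk <- trs[[2]]@rotation
  manual <- as.numeric(Rki %*% Rjk %*% r[[1]] + Rki %*% r[[2]] + r[[3]])
  expect_equal(got, manual, tolerance = 1e-14)
  expect_lte(sqrt(sum(got^2)), 3 * max(sapply(r, function(v)
    sqrt(sum(v^2)))))
})

test_that("a non-closing rotation cycle triggers a warning", {
  trs <- list(RigidTransform(0.3), RigidTransform(0.3),
              RigidTransform(0.3))
  expect_warning(cycleBoundCheck(trs, list(c(0, 0), c(0, 0), c(0, 0))),
                 "does not close")
})

test_that("transforms are recovered exactly from a noiseless match graph", {
  g <- generateMatchGraph(n_features = 60L, n_bands = 4L, seed = 2L)
  ch <- composeChains(g$matchGraph, g$featureSets)
  fl <- filterOutliers(ch)
  ts <- estimateTransforms(fl$inliers, g$featureSets)
  for (b in 2:4) {
    tr <- ts@transforms[[b]]
    tt <- g$truth$trueTransforms[[b]]
    expect_equal(tr@rotation, tt@rotation, tolerance = 1e-9)
    expect_equal(tr@translation, tt@translation, tolerance = 1e-8)
  }
})

test_that("registerCube with identity transforms returns the input", {
  ph <- defaultPhantom()
  nb <- nBands(ph$cube)
  ts <- new("TransformSet", referenceBand = 1L,
            transforms = rep(list(RigidTransform()), nb),
            residuals = rep(0, nb))
  out <- registerCube(ph$cube, ts, interpolation = "nearest")
  expect_equal(out@data, ph$cube@data)
})

test_that("a missing band transform is reported by name", {
  ph <- defaultPhantom()
  ts <- new("TransformSet", referenceBand = 1L,
            transforms = rep(list(RigidTransform()), 3L),
            residuals = rep(0, 3L))
  expect_error(registerCube(ph$cube, ts), "transform")
})

test_that("true transforms align every band mask with the reference", {
  ph <- defaultPhantom()
  nb <- nBands(ph$cube)
  d <- dim(ph$cube@data)
  bandMasks <- array(FALSE, d)
  for (b in seq_len(nb))
    bandMasks[b, , ] <- warpImage(1 * ph$truth@vesselMask,
                                  invertTransform(ph$truth@trueTransforms[[b]]),
                                  interpolation = "nearest", fill = 0) > 0.5
  ms <- MaskStack(bandMasks, "levelset")
  ts <- new("TransformSet", referenceBand = 1L,
            transforms = ph$truth@trueTransforms, residuals = rep(0, nb))
  reg <- registerMasks(ms, ts)
  ref <- getBand(ms, 1L)
  for (b in seq_len(nb)) {
    m <- getBand(reg, b)
    dice <- 2 * sum(m & ref) / (sum(m) + sum(ref))
    expect_gte(dice, 0.98)
  }
})

test_that("the full estimation front-end reports consistent statistics", {
  est <- defaultRegistration()
  expect_equal(est$stats$raw,
               est$stats$retained + est$stats$incomplete +
                 sum(est$filtered$outliers@complete))
  expect_equal(length(est$filtered$inliers), est$stats$retained)
  expect_s4_class(est$transformSet, "TransformSet")
  expect_equal(est$transformSet@referenceBand, 1L)
  expect_equal(est$transformSet@transforms[[1L]]@rotation, diag(2))
})
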