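# Shared fixtures, computed once per session and cached: the default
# phantom and its segmentation/registration are used by several files.
.fixtureCache <- new.env(parent = emptyenv())

defaultPhantom <- function() {
  if (is.null(.fixtureCache$ph))
    .fixtureCache$ph <- generatePhantom(phantomSpec(seed = 1L))
  .fixtureCache$ph
}

defaultMasks <- function() {
  if (is.null(.fixtureCache$masks))
    .fixtureCache$masks <- segmentCube(defaultPhantom()$cube)
  .fixtureCache$masks
}

defaultRegistration <- function() {
  if (is.null(.fixtureCache$est))
    .fixtureCache$est <- estimateCubeTransforms(defaultPhantom()$cube)
  .fixtureCache$est
}

defaultFeatureSets <- function() {
  if (is.null(.fixtureCache$fs)) {
    masks <- defaultMasks()
    .fixtureCache$fs <- lapply(seq_len(nBands(masks)), function(b)
      detectFeatures(getBand(masks, b)))
  }
  .fixtureCache$fs
}

# Independent exhaustive-search oracle for the Otsu threshold: evaluates
# the between-class variance at every candidate split of the sorted unique
# values and returns the argmax level (smallest level on ties).
bruteForceOtsu <- function(x) {
  x <- as.numeric(x)
  u <- sort(unique(x))
  n <- length(x)
  best <- -1
  bestT <- u[1L]
  for (k in seq_len(length(u) - 1L)) {
    t <- u[k]
    in0 <- x <= t
    w0 <- mean(in0)
    w1 <- 1 - w0
    sb2 <- w0 * w1 * (mean(x[!in0]) - mean(x[in0]))^2
    if (sb2 > best + 1e-15 * max(1, abs(best))) {
      best <- sb2
      bestT <- t
    }
  }
  bestT
}

# True transform mapping band b's frame into band ref's frame, from a
# PhantomTruth (whose transforms map each band into band 1's frame).
truthBandToRef <- function(truth, b, ref = 1L) {
  composeTransforms(invertTransform(truth@trueTransforms[[ref]]),
                    truth@trueTransforms[[b]])
}
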