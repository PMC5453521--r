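# Synthetic hyperspectral vessel phantom with full ground truth.  The
# phantom emulates what the pipeline must survive on real window-chamber
# stacks: a dark vessel tree on bright tissue, capillary clutter,
# band-dependent global gain (transmittance variation), per-band rigid
# jitter (animal motion) and additive sensor noise, with a two-end-member
# Beer-Lambert absorption model driving the spectral dimension.

#' Phantom specification
#'
#' Defaults define the standard test conditions: 10 bands at 128 x 128 px,
#' translations up to 5 px and rotations up to 2 degrees of per-band
#' jitter, band gains spanning 0.7-1.0, and additive Gaussian noise of 8
#' DN on a 12-bit range.  Vessel geometry (including capillary clutter) is
#' reproducible for a given spec and independent of \code{seed}, which
#' controls only jitter, gains and noise.
#'
#' @param shape integer (bands, rows, cols).
#' @param wavelengths per-band wavelengths in nm (default: linear
#'   550-1000 nm).
#' @param vessel_width main-vessel diameter in px.
#' @param n_capillaries number of short thin clutter segments.
#' @param jitter_translation_max max |translation| per axis, px.
#' @param jitter_rotation_max max |rotation|, degrees.
#' @param band_gain_range multiplicative per-band gain range.
#' @param noise_sd additive Gaussian noise sd, DN.
#' @param so2_field per-pixel true saturation in [0, 1] (matrix rows x
#'   cols, or a single value); default: smooth 0.6-0.9 left-right ramp.
#' @param extinction an [extinctionTable()] on this wavelength grid;
#'   default: two smooth well-separated synthetic spectra.
#' @param absorption_strength peak vessel absorbance scale (decadic OD).
#' @param bit_depth sample bit depth.
#' @param quantize round samples to integer DN (TRUE for realistic cubes;
#'   FALSE for exact forward-model inversion checks).
#' @param seed integer RNG seed for jitter, gains and noise.
#' @return a validated list consumed by [generatePhantom()].
#' @export
phantomSpec <- function(shape = c(10L, 128L, 128L),
                        wavelengths = NULL,
                        vessel_width = 12,
                        n_capillaries = 40L,
                        jitter_translation_max = 5,
                        jitter_rotation_max = 2,
                        band_gain_range = c(0.7, 1.0),
                        noise_sd = 8,
                        so2_field = NULL,
                        extinction = NULL,
                        absorption_strength = 1.0,
                        bit_depth = 12L,
                        quantize = TRUE,
                        seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            vessel_width >= 1, vessel_width < min(shape[2:3]),
            jitter_translation_max >= 0, jitter_rotation_max >= 0,
            noise_sd >= 0, length(band_gain_range) == 2L,
            all(band_gain_range > 0))
  if (is.null(wavelengths))
    wavelengths <- seq(550, 1000, length.out = shape[1L])
  if (is.null(so2_field))
    so2_field <- matrix(rep(seq(0.6, 0.9, length.out = shape[3L]),
                            each = shape[2L]), shape[2L], shape[3L])
  if (length(so2_field) == 1L)
    so2_field <- matrix(so2_field, shape[2L], shape[3L])
  stopifnot(all(so2_field >= 0), all(so2_field <= 1))
  if (is.null(extinction)) {
    wl <- wavelengths
    extinction <- extinctionTable(
      wl,
      eps_o2hb = 0.3 + 1.4 * exp(-((wl - 600) / 60)^2) +
        0.3 * exp(-((wl - 900) / 80)^2),
      eps_hhb = 0.3 + 1.4 * exp(-((wl - 730) / 80)^2) +
        0.5 * exp(-((wl - 560) / 40)^2))
  }
  list(shape = shape, wavelengths = as.numeric(wavelengths),
       vessel_width = vessel_width, n_capillaries = as.integer(n_capillaries),
       jitter_translation_max = jitter_translation_max,
       jitter_rotation_max = jitter_rotation_max,
       band_gain_range = band_gain_range, noise_sd = noise_sd,
       so2_field = so2_field, extinction = extinction,
       absorption_strength = absorption_strength,
       bit_depth = as.integer(bit_depth), quantize = quantize,
       seed = as.integer(seed))
}

# run fun() under a local RNG state seeded with `seed`
.withSeed <- function(seed, fun) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fun()
}

# Stamp a tube of varying half-width along sampled centerline points into a
# thickness field (relative chord length through a cylinder, 0..1).
.stampTube <- function(thick, pr, pc, halfw, weight = 1) {
  nr <- nrow(thick); nc <- ncol(thick)
  for (i in seq_along(pr)) {
    h <- halfw[i]
    r0 <- max(1L, floor(pr[i] - h)); r1 <- min(nr, ceiling(pr[i] + h))
    c0 <- max(1L, floor(pc[i] - h)); c1 <- min(nc, ceiling(pc[i] + h))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - pr[i])^2, (cc - pc[i])^2, "+")
    t <- sqrt(pmax(0, 1 - d2 / h^2)) * weight
    thick[rr, cc] <- pmax(thick[rr, cc], t)
  }
  thick
}

# Deterministic vessel + capillary geometry for a given spec (independent
# of the jitter/noise seed).
.phantomGeometry <- function(spec) {
  nr <- spec$shape[2L]; nc <- spec$shape[3L]
  .withSeed(760341L + nr * 7L + nc + spec$n_capillaries, function() {
    nCtrl <- 6L
    cx <- seq(0, nc - 1, length.out = nCtrl)
    cy <- nr / 2 + runif(nCtrl, -nr / 4, nr / 4)
    f <- splinefun(cx, cy, method = "natural")
    s <- seq(0, nc - 1, by = 0.25)
    pr <- pmin(pmax(f(s), 2), nr - 3)
    pc <- s
    # smooth caliber modulation along the vessel
    halfw <- (spec$vessel_width / 2) *
      (0.85 + 0.3 * sin(2 * pi * s / nc * 1.7 + 0.8))
    thick <- matrix(0, nr, nc)
    thick <- .stampTube(thick, pr + 1, pc + 1, halfw)
    # truth support at the FWHM of the chord profile: the optical tail where
    # the projected cylinder thins to a sliver is not meaningfully "vessel"
    vesselMask <- thick >= 0.5
    fullSupport <- thick > 0
    # capillary clutter: short, thin, weakly absorbing segments
    capThick <- matrix(0, nr, nc)
    for (k in seq_len(spec$n_capillaries)) {
      p0 <- c(runif(1, 5, nr - 5), runif(1, 5, nc - 5))
      ang <- runif(1, 0, pi)
      len <- runif(1, 8, 18)
      t <- seq(0, len, by = 0.5)
      capThick <- .stampTube(capThick, p0[1L] + t * sin(ang),
                             p0[2L] + t * cos(ang),
                             rep(0.9, length(t)), weight = 0.45)
    }
    capThick[fullSupport] <- 0
    list(thickness = thick, capillary = capThick, vesselMask = vesselMask)
  })
}

#' Generate a synthetic hyperspectral vessel phantom
#'
#' Builds a smooth dark vessel of varying caliber on a bright tissue
#' background plus thin capillary clutter; computes per-pixel transmitted
#' intensity from the saturation field through the two-end-member
#' Beer-Lambert model at each wavelength; applies per-band gain, per-band
#' rigid jitter sampled within the spec maxima, and additive Gaussian
#' noise.  Band 1 carries identity jitter, so the reference frame is band
#' 1's frame and truth transforms compare directly with estimates.
#' Deterministic for a fixed spec.
#'
#' @param spec a [phantomSpec()].
#' @return list with \code{cube} (a [HyperCube]) and \code{truth} (a
#'   [PhantomTruth]); the per-band incident intensities (gain times
#'   background level, the \code{reference} for [absorbance()]) are
#'   attached to the truth as attribute \code{"reference"}.
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  nb <- spec$shape[1L]; nr <- spec$shape[2L]; nc <- spec$shape[3L]
  geom <- .phantomGeometry(spec)
  maxDN <- 2^spec$bit_depth - 1
  I0 <- 0.85 * maxDN
  so2 <- spec$so2_field
  epsO <- spec$extinction$eps_o2hb
  epsH <- spec$extinction$eps_hhb
  epsRef <- max(epsO, epsH)
  # per-pixel end-member mixing weights (oxy, deoxy)
  abund <- rbind(as.numeric(so2), 1 - as.numeric(so2))
  .withSeed(spec$seed, function() {
    gains <- runif(nb, spec$band_gain_range[1L], spec$band_gain_range[2L])
    trs <- vector("list", nb)
    trs[[1L]] <- RigidTransform()
    center <- c((nr - 1) / 2, (nc - 1) / 2)
    if (nb > 1L) for (b in 2:nb) {
      ang <- runif(1, -1, 1) * spec$jitter_rotation_max * pi / 180
      tsl <- runif(2, -1, 1) * spec$jitter_translation_max
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
      trs[[b]] <- new("RigidTransform", rotation = R,
                      translation = as.numeric(center - R %*% center + tsl))
    }
    data <- array(0, spec$shape)
    for (b in seq_len(nb)) {
      mu <- so2 * epsO[b] + (1 - so2) * epsH[b]
      dA <- spec$absorption_strength / epsRef * mu *
        (geom$thickness + geom$capillary)
      scene <- I0 * gains[b] * 10^(-dA)
      img <- if (b == 1L) scene else
        warpImage(scene, invertTransform(trs[[b]]), "bilinear",
                  fill = I0 * gains[b])
      if (spec$noise_sd > 0)
        img <- img + rnorm(length(img), 0, spec$noise_sd)
      img <- pmin(pmax(img, 0), maxDN)
      if (spec$quantize) img <- round(img)
      data[b, , ] <- img
    }
    truth <- new("PhantomTruth", trueTransforms = trs,
                 vesselMask = geom$vesselMask,
                 abundances = abund,
                 spectra = cbind(o2hb = epsO, hhb = epsH),
                 so2 = so2)
    attr(truth, "reference") <- I0 * gains
    list(cube = HyperCube(data, spec$wavelengths, spec$bit_depth),
         truth = truth)
  })
}

#' Generate a synthetic closed-loop match graph with planted outliers
#'
#' Plants rigid per-band maps and index-faithful correspondences for
#' \code{n_features} keypoints over \code{n_bands} bands, perturbs each
#' band's coordinates by bounded noise, and corrupts the loop-closing
#' matches of exactly \code{floor(outlier_fraction * n_features)} features
#' by redirecting them (in swap pairs, plus one 3-cycle if the count is
#' odd) to other features at least \code{min_outlier_displacement} px away
#' in the first band.  Inlier chains therefore return to their own
#' first-band keypoint (closure distance 0); outlier chains land beyond
#' the displacement floor.
#'
#' @param n_features number of planted features.
#' @param n_bands number of bands in the loop (>= 3).
#' @param outlier_fraction fraction in [0, 1).
#' @param noise_sd bound on the per-band coordinate perturbation norm, px.
#' @param seed integer RNG seed.
#' @param min_outlier_displacement minimum first-band distance between a
#'   corrupted chain's seed and landing keypoints, px.
#' @param field_size side of the square coordinate field, px.
#' @return list with \code{featureSets} (per-band [FeatureSet]s,
#'   descriptors unused), \code{matchGraph} (list of [PairMatches]
#'   covering the closed loop) and \code{truth} (outlier labels, true
#'   transforms, base positions).
#' @export
generateMatchGraph <- function(n_features = 100L, n_bands = 3L,
                               outlier_fraction = 0, noise_sd = 0,
                               seed = 1L,
                               min_outlier_displacement = 10,
                               field_size = 128) {
  stopifnot(outlier_fraction >= 0, outlier_fraction < 1, n_bands >= 3L,
            n_features >= 2L)
  .withSeed(seed, function() {
    margin <- 10
    X1 <- cbind(runif(n_features, margin, field_size - margin),
                runif(n_features, margin, field_size - margin))
    trs <- vector("list", n_bands)
    trs[[1L]] <- RigidTransform()
    for (b in 2:n_bands) {
      ang <- runif(1, -1, 1) * 2 * pi / 180
      trs[[b]] <- RigidTransform(angle = ang,
                                 translation = runif(2, -5, 5))
    }
    featureSets <- lapply(seq_len(n_bands), function(b) {
      pos <- applyTransform(invertTransform(trs[[b]]), X1)
      if (noise_sd > 0) {
        ang <- runif(n_features, 0, 2 * pi)
        rad <- runif(n_features, 0, noise_sd)
        pos <- pos + cbind(rad * sin(ang), rad * cos(ang))
      }
      new("FeatureSet",
          points = data.frame(row = pos[, 1L], col = pos[, 2L],
                              scale = 1, orientation = 0, response = 1),
          descriptors = matrix(0, n_features, 1L), detector = "planted")
    })
    identityPairs <- data.frame(idxA = seq_len(n_features),
                                idxB = seq_len(n_features), distance = 0)
    loop <- c(seq_len(n_bands), 1L)
    matchGraph <- lapply(seq_len(n_bands), function(k)
      new("PairMatches", bandA = loop[k], bandB = loop[k + 1L],
          pairs = identityPairs))
    nOut <- floor(outlier_fraction * n_features)
    outlier <- logical(n_features)
    if (nOut > 0L) {
      ord <- sample.int(n_features)
      # greedily pick outliers so that cyclic neighbours in the list are
      # far enough apart in band 1 for the planted displacement floor
      sel <- integer(0)
      for (i in ord) {
        if (length(sel) == nOut) break
        if (!length(sel) ||
            all(sqrt(rowSums((X1[sel, , drop = FALSE] -
                              matrix(X1[i, ], length(sel), 2L,
                                     byrow = TRUE))^2)) >
                min_outlier_displacement))
          sel <- c(sel, i)
      }
      if (length(sel) < nOut)
        stop("could not place ", nOut, " outliers at the requested ",
             "displacement; enlarge field_size or lower the floor")
      if (length(sel) == 1L) {
        # a single corrupted match cannot stay one-to-one without a swap
        # partner; take the farthest feature as partner and label both
        j <- which.max(rowSums((X1 - matrix(X1[sel, ], n_features, 2L,
                                            byrow = TRUE))^2))
        sel <- c(sel, j)
        warning("outlier count rounded up to 2 to keep matching one-to-one")
      }
      outlier[sel] <- TRUE
      closing <- matchGraph[[n_bands]]@pairs
      # redirect loop-closing matches along a cycle over the outlier set,
      # keeping the match one-to-one
      perm <- c(sel[-1L], sel[1L])
      closing$idxB[sel] <- perm
      matchGraph[[n_bands]] <- new("PairMatches", bandA = n_bands,
                                   bandB = 1L, pairs = closing)
    }
    list(featureSets = featureSets, matchGraph = matchGraph,
         truth = list(outlier = outlier, trueTransforms = trs,
                      positions = X1))
  })
}
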