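# Cycle-consistency match filtering and rigid cube registration.  Adjacent-
# band matches are chained around the closed band loop 1 -> 2 -> ... -> N
# -> 1; a chain whose loop-closure distance in band 1's frame exceeds delta
# is discarded as an outlier, the analytic justification being that three
# chained inlier links (per-link residual norm <= epsilon) can accumulate a
# closure residual of at most 3 * epsilon.

#' Chain-filter parameters
#'
#' @param delta closure-distance threshold in px (default 10, chosen in
#'   negative correlation to data quality: cleaner stacks tolerate a
#'   smaller cut).
#' @param epsilon per-link inlier residual threshold in px, used by the
#'   cycle-bound diagnostics.
#' @param n_bands_used number of bands participating in the chain loop
#'   (>= 3).
#' @export
chainFilterParams <- function(delta = 10, epsilon = 1,
                              n_bands_used = NULL) {
  stopifnot(delta > 0, epsilon > 0)
  if (!is.null(n_bands_used)) stopifnot(n_bands_used >= 3L)
  list(delta = delta, epsilon = epsilon, n_bands_used = n_bands_used)
}

#' Compose adjacent-band matches into closed chains
#'
#' Follows single best matches greedily from every first-band feature that
#' has an outgoing match, through every band in the loop and back to the
#' first band via the loop-closing match set.  A track that hits a feature
#' with no match in the next band is marked incomplete.  The closure
#' distance is the Euclidean distance, in the first band's frame, between
#' the seed keypoint and the keypoint the loop returned to.
#'
#' @param matchGraph list of [PairMatches] covering the closed loop:
#'   (b1, b2), (b2, b3), ..., (bN, b1).
#' @param featureSets list of [FeatureSet]s indexed by band.
#' @return a [ChainSet].
#' @export
composeChains <- function(matchGraph, featureSets) {
  if (!length(matchGraph)) stop("empty match graph")
  bands <- vapply(matchGraph, function(m) m@bandA, integer(1L))
  closes <- matchGraph[[length(matchGraph)]]@bandB
  for (k in seq_len(length(matchGraph) - 1L))
    if (matchGraph[[k]]@bandB != matchGraph[[k + 1L]]@bandA)
      stop("match graph is not a consecutive chain at link ", k)
  if (closes != bands[1L])
    stop("configuration error: loop not closed (missing matches from band ",
         matchGraph[[length(matchGraph)]]@bandA, " back to band ",
         bands[1L], ")")
  maps <- lapply(matchGraph, function(m) {
    lut <- integer(0)
    if (nrow(m@pairs))
      lut <- stats::setNames(m@pairs$idxB, m@pairs$idxA)
    lut
  })
  firstMap <- maps[[1L]]
  seeds <- sort(as.integer(names(firstMap)))
  nL <- length(matchGraph)
  n <- length(seeds)
  featureIndex <- matrix(NA_integer_, n, nL + 1L)
  complete <- logical(n)
  pts1 <- featureSets[[bands[1L]]]@points
  startCoord <- matrix(NA_real_, n, 2L)
  endCoord <- matrix(NA_real_, n, 2L)
  closure <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    cur <- seeds[r]
    featureIndex[r, 1L] <- cur
    ok <- TRUE
    for (k in seq_len(nL)) {
      nxt <- maps[[k]][as.character(cur)]
      if (is.na(nxt)) { ok <- FALSE; break }
      cur <- as.integer(nxt)
      featureIndex[r, k + 1L] <- cur
    }
    startCoord[r, ] <- c(pts1$row[seeds[r]], pts1$col[seeds[r]])
    if (ok) {
      complete[r] <- TRUE
      endCoord[r, ] <- c(pts1$row[cur], pts1$col[cur])
      closure[r] <- sqrt(sum((startCoord[r, ] - endCoord[r, ])^2))
    }
  }
  new("ChainSet", featureIndex = featureIndex, startCoord = startCoord,
      endCoord = endCoord, closureDistance = closure, complete = complete,
      bands = as.integer(bands))
}

.subsetChains <- function(chains, sel) {
  new("ChainSet",
      featureIndex = chains@featureIndex[sel, , drop = FALSE],
      startCoord = chains@startCoord[sel, , drop = FALSE],
      endCoord = chains@endCoord[sel, , drop = FALSE],
      closureDistance = chains@closureDistance[sel],
      complete = chains@complete[sel], bands = chains@bands)
}

#' Split chains into inliers and outliers by closure distance
#'
#' Complete chains with closure distance at most \code{delta} are inliers;
#' incomplete chains and chains above \code{delta} are outliers.  Raw and
#' retained match counts (the RM/CM bookkeeping) are returned alongside.
#'
#' @param chains a [ChainSet] from [composeChains()].
#' @param params a [chainFilterParams()] list.
#' @return list with elements \code{inliers}, \code{outliers} (both
#'   [ChainSet]) and \code{stats} (raw, retained, incomplete counts and the
#'   delta used).
#' @export
filterOutliers <- function(chains, params = chainFilterParams()) {
  ok <- chains@complete & chains@closureDistance <= params$delta
  ok[is.na(ok)] <- FALSE
  list(inliers = .subsetChains(chains, ok),
       outliers = .subsetChains(chains, !ok),
       stats = list(raw = length(chains@complete),
                    retained = sum(ok),
                    incomplete = sum(!chains@complete),
                    delta = params$delta))
}

#' Closure residual of a three-link cycle
#'
#' For transforms mapping band i to j, j to k and k back to i, with
#' per-link residual vectors \eqn{r_{ij}, r_{jk}, r_{ki}}, the residual
#' accumulated around the closed cycle is
#' \eqn{r_{ii'} = R_{ki} R_{jk} r_{ij} + R_{ki} r_{jk} + r_{ki}}; when each
#' link residual has norm at most \eqn{\epsilon}, its norm is bounded by
#' \eqn{3\epsilon} because rotations preserve norms.
#'
#' @param perLinkTransforms list of three [RigidTransform]s
#'   (i->j, j->k, k->i).
#' @param perLinkResiduals list of three numeric length-2 residual vectors.
#' @return the composed residual 2-vector \eqn{r_{ii'}}.
#' @export
cycleBoundCheck <- function(perLinkTransforms, perLinkResiduals) {
  stopifnot(length(perLinkTransforms) == 3L, length(perLinkResiduals) == 3L)
  Rij <- perLinkTransforms[[1L]]@rotation
  Rjk <- perLinkTransforms[[2L]]@rotation
  Rki <- perLinkTransforms[[3L]]@rotation
  if (max(abs(Rki %*% Rjk %*% Rij - diag(2))) > 1e-6)
    warning("cycle does not close: composed rotation is far from identity")
  as.numeric(Rki %*% Rjk %*% perLinkResiduals[[1L]] +
             Rki %*% perLinkResiduals[[2L]] +
             perLinkResiduals[[3L]])
}

#' Least-squares rigid transform between paired point sets
#'
#' Finds the rotation + translation (no scaling) minimizing
#' \eqn{\sum_i \| b_i - (R a_i + T) \|^2} (2-D orthogonal Procrustes with
#' the reflection excluded).
#'
#' @param pointsA,pointsB n x 2 matrices of paired (row, col) coordinates;
#'   the transform maps A onto B.
#' @return a [RigidTransform] with the RMS residual attached as attribute
#'   \code{"rms"}.
#' @export
estimateRigid <- function(pointsA, pointsB) {
  A <- rbind2mat(pointsA); B <- rbind2mat(pointsB)
  if (nrow(A) < 2L || nrow(A) != nrow(B))
    stop("need at least 2 point pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  if (max(abs(Ac)) < 1e-12 || max(abs(Bc)) < 1e-12)
    stop("points are coincident; rigid transform is underdetermined")
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  tr <- as.numeric(cb - R %*% ca)
  out <- new("RigidTransform", rotation = R, translation = tr)
  res <- B - applyTransform(out, A)
  attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
  out
}

#' Estimate per-band transforms from surviving inlier chains
#'
#' For each band in the loop, the coordinates of the inlier chains'
#' keypoints in that band are paired with the same chains' first-band
#' coordinates and a rigid transform band -> reference is fitted directly
#' (composing adjacent-pair estimates is available as a comparison mode but
#' accumulates error over long loops).  The reference band is the first
#' band of the chain loop.
#'
#' @param chains an inlier [ChainSet].
#' @param featureSets list of [FeatureSet]s indexed by band.
#' @param method \code{"direct"} (default) or \code{"compose"}.
#' @return a [TransformSet] over the loop's bands (transform list indexed
#'   by position in \code{chains@bands}).
#' @export
estimateTransforms <- function(chains, featureSets,
                               method = c("direct", "compose")) {
  method <- match.arg(method)
  bands <- chains@bands
  nL <- length(bands)
  if (length(chains) < 2L)
    stop("need at least 2 inlier chains to estimate transforms")
  coords <- function(pos) {
    b <- bands[pos]
    idx <- chains@featureIndex[, pos]
    pts <- featureSets[[b]]@points
    cbind(pts$row[idx], pts$col[idx])
  }
  ref <- coords(1L)
  trs <- vector("list", nL)
  res <- rep(NA_real_, nL)
  trs[[1L]] <- RigidTransform()
  res[1L] <- 0
  # trimmed least squares: a feature can re-detect at a consistently shifted
  # spot in every band (so it passes the closure filter) yet still be poorly
  # localized; iteratively drop points whose residual is an outlier of the
  # residual distribution (median + 3*MAD) and refit
  robustRigid <- function(a, b) {
    keep <- seq_len(nrow(a))
    tr <- estimateRigid(a, b)
    for (it in 1:5) {
      if (length(keep) <= 3L) break
      r <- sqrt(rowSums((applyTransform(tr, a[keep, , drop = FALSE]) -
                           b[keep, , drop = FALSE])^2))
      cut <- stats::median(r) + 3 * stats::mad(r)
      if (all(r <= cut)) break
      keep <- keep[r <= cut]
      tr <- estimateRigid(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
    }
    tr
  }
  if (method == "direct") {
    for (j in 2:nL) {
      tr <- robustRigid(coords(j), ref)
      res[j] <- attr(tr, "rms")
      attr(tr, "rms") <- NULL
      trs[[j]] <- tr
    }
  } else {
    acc <- RigidTransform()
    for (j in 2:nL) {
      tr <- robustRigid(coords(j), coords(j - 1L))
      res[j] <- attr(tr, "rms")
      attr(tr, "rms") <- NULL
      acc <- composeTransforms(acc, tr)
      trs[[j]] <- acc
    }
  }
  new("TransformSet", referenceBand = 1L, transforms = trs,
      residuals = res)
}

#' Resample a cube into the reference band's frame
#'
#' Applies each band's rigid transform; the reference band is passed
#' through unchanged, out-of-frame samples take \code{fill}, and
#' wavelengths are preserved.
#'
#' @param cube a [HyperCube].
#' @param transformSet a [TransformSet] with one transform per band of the
#'   cube.
#' @param interpolation \code{"bilinear"} (default) or \code{"nearest"}.
#' @param fill fill value for out-of-frame pixels.
#' @return the registered [HyperCube].
#' @export
registerCube <- function(cube, transformSet,
                         interpolation = c("bilinear", "nearest"),
                         fill = 0) {
  interpolation <- match.arg(interpolation)
  validObject(cube)
  nb <- nBands(cube)
  if (length(transformSet@transforms) != nb)
    stop("missing band transform: transform set covers ",
         length(transformSet@transforms), " bands, cube has ", nb)
  out <- cube@data
  for (b in seq_len(nb)) {
    if (b == transformSet@referenceBand) next
    out[b, , ] <- warpImage(getBand(cube, b),
                            transformSet@transforms[[b]],
                            interpolation, fill)
  }
  HyperCube(pmin(pmax(out, 0), 2^cube@bitDepth - 1), cube@wavelengths,
            cube@bitDepth)
}

#' Resample a mask stack into the reference band's frame
#'
#' Nearest-neighbor warping of each band's binary mask.
#'
#' @param stack a [MaskStack].
#' @param transformSet a [TransformSet] with one transform per band.
#' @return the registered [MaskStack].
#' @export
registerMasks <- function(stack, transformSet) {
  nb <- nBands(stack)
  out <- stack@masks
  for (b in seq_len(nb)) {
    if (b == transformSet@referenceBand) next
    out[b, , ] <- warpImage(1 * getBand(stack, b),
                            transformSet@transforms[[b]],
                            "nearest", 0) > 0.5
  }
  MaskStack(out, stack@provenance)
}

#' Run segmentation, matching, cycle filtering and transform estimation
#'
#' The full estimation front-end of the registration scheme: segment each
#' selected band, detect and match keypoints between consecutive selected
#' bands plus the loop-closing pair, compose and filter chains by closure
#' distance, and fit per-band rigid transforms from the surviving chains.
#'
#' @param cube a [HyperCube].
#' @param bands band subset forming the loop (default: all bands).
#' @param window Otsu window size in px.
#' @param lsParams a [levelSetParams()] list.
#' @param detector detector name for [detectFeatures()].
#' @param ratio Lowe ratio for [matchAdjacent()].
#' @param params a [chainFilterParams()] list.
#' @return list with \code{transformSet} (over all cube bands; bands
#'   outside the loop get identity), \code{chains}, \code{filtered},
#'   \code{masks}, \code{featureSets}, \code{stats}.
#' @export
estimateCubeTransforms <- function(cube, bands = seq_len(nBands(cube)),
                                   window = 50L,
                                   lsParams = levelSetParams(),
                                   detector = "hessian", ratio = 0.8,
                                   params = chainFilterParams()) {
  stopifnot(length(bands) >= 3L)
  masks <- segmentCube(cube, window, lsParams)
  featureSets <- vector("list", nBands(cube))
  for (b in bands)
    featureSets[[b]] <- detectFeatures(getBand(masks, b), detector)
  loop <- c(bands, bands[1L])
  matchGraph <- lapply(seq_len(length(loop) - 1L), function(k)
    matchAdjacent(featureSets[[loop[k]]], featureSets[[loop[k + 1L]]],
                  ratio, bandA = loop[k], bandB = loop[k + 1L]))
  chains <- composeChains(matchGraph, featureSets)
  filtered <- filterOutliers(chains, params)
  if (length(filtered$inliers) < 2L)
    stop("registration failed: only ", length(filtered$inliers),
         " inlier chains survive the closure filter (delta = ",
         params$delta, ")")
  loopSet <- estimateTransforms(filtered$inliers, featureSets)
  trs <- rep(list(RigidTransform()), nBands(cube))
  res <- rep(NA_real_, nBands(cube))
  for (j in seq_along(bands)) {
    trs[[bands[j]]] <- loopSet@transforms[[j]]
    res[bands[j]] <- loopSet@residuals[j]
  }
  ts <- new("TransformSet", referenceBand = as.integer(bands[1L]),
            transforms = trs, residuals = res)
  list(transformSet = ts, chains = chains, filtered = filtered,
       masks = masks, featureSets = featureSets,
       stats = filtered$stats)
}

#' Serialize a TransformSet as a plain-text table
#'
#' Columns: band, angle (radians), translation rows/cols, RMS residual.
#'
#' @param transformSet a [TransformSet].
#' @param path output TSV path.
#' @export
exportTransforms <- function(transformSet, path) {
  tab <- data.frame(
    band = seq_along(transformSet@transforms),
    angle = vapply(transformSet@transforms, transformAngle, numeric(1L)),
    t_row = vapply(transformSet@transforms,
                   function(t) t@translation[1L], numeric(1L)),
    t_col = vapply(transformSet@transforms,
                   function(t) t@translation[2L], numeric(1L)),
    rms_residual = transformSet@residuals)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
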