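#' @import methods
#' @importFrom stats sd var quantile rnorm runif median splinefun optimize
#' @importFrom utils head tail modifyList
NULL

#' HyperCube: a hyperspectral image cube
#'
#' Container for a band-major hyperspectral intensity cube together with the
#' per-band wavelength grid and the acquisition bit depth.  The array is
#' indexed \code{[band, row, col]}; stored values lie in
#' \code{[0, 2^bitDepth - 1]}.  All pipeline stages consume and produce this
#' class.
#'
#' @slot data numeric 3-D array, \code{bands x rows x cols}, non-negative.
#' @slot wavelengths numeric vector of per-band wavelengths in nm, strictly
#'   increasing, one per band.
#' @slot bitDepth integer; the stored-value range is
#'   \code{[0, 2^bitDepth - 1]}.
#'
#' @seealso [readBSQ()], [writeBSQ()], [segmentCube()], [registerCube()]
#' @export
setClass("HyperCube",
  representation(data = "array", wavelengths = "numeric",
                 bitDepth = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@data)) != 3L)
      msgs <- c(msgs, "data must be a 3-D array (bands x rows x cols)")
    else {
      nb <- dim(object@data)[1L]
      if (length(object@wavelengths) != nb)
        msgs <- c(msgs, sprintf(
          "number of wavelengths (%d) must equal number of bands (%d)",
          length(object@wavelengths), nb))
    }
    if (length(object@wavelengths) > 1L &&
        any(diff(object@wavelengths) <= 0))
      msgs <- c(msgs, "wavelengths must be strictly increasing")
    if (length(object@bitDepth) != 1L || is.na(object@bitDepth) ||
        object@bitDepth < 1L)
      msgs <- c(msgs, "bitDepth must be a single positive integer")
    else {
      rng <- range(object@data)
      if (rng[1L] < 0 || rng[2L] > 2^object@bitDepth - 1)
        msgs <- c(msgs, sprintf(
          "intensities must lie within [0, %d] for bitDepth %d",
          2^object@bitDepth - 1, object@bitDepth))
    }
    if (length(msgs)) msgs else TRUE
  })

#' MaskStack: per-band binary vessel masks
#'
#' Boolean stack aligned with a source [HyperCube]: one vessel mask per band,
#' \code{TRUE} = vessel foreground.  \code{provenance} records which
#' segmentation stage produced it (\code{"threshold"} for the windowed-Otsu
#' stage, \code{"levelset"} after contour filtering).
#'
#' @slot masks logical 3-D array, \code{bands x rows x cols}.
#' @slot provenance character, \code{"threshold"} or \code{"levelset"}.
#' @export
setClass("MaskStack",
  representation(masks = "array", provenance = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(dim(object@masks)) != 3L)
      msgs <- c(msgs, "masks must be a 3-D array")
    if (!is.logical(object@masks))
      msgs <- c(msgs, "masks must be logical")
    if (!object@provenance %in% c("threshold", "levelset"))
      msgs <- c(msgs, "provenance must be 'threshold' or 'levelset'")
    if (length(msgs)) msgs else TRUE
  })

#' FeatureSet: interest points with descriptors for one band
#'
#' Sub-pixel keypoints detected on a binary vessel mask.  \code{points} has
#' one row per keypoint with columns \code{row}, \code{col} (0-based,
#' sub-pixel), \code{scale} (detection scale in px), \code{orientation}
#' (radians) and \code{response}; \code{descriptors} holds one fixed-length
#' descriptor per row, aligned with \code{points}.
#'
#' @slot points data.frame of keypoint geometry.
#' @slot descriptors numeric matrix, one row per keypoint.
#' @slot detector character, name of the detector that produced the set.
#' @export
setClass("FeatureSet",
  representation(points = "data.frame", descriptors = "matrix",
                 detector = "character"),
  validity = function(object) {
    msgs <- character()
    need <- c("row", "col", "scale", "orientation", "response")
    if (!all(need %in% names(object@points)))
      msgs <- c(msgs, paste("points must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(object@points) != nrow(object@descriptors))
      msgs <- c(msgs, "points and descriptors must have equal row counts")
    if (length(msgs)) msgs else TRUE
  })

#' PairMatches: one-to-one descriptor matches between two bands
#'
#' The correspondence set between the feature sets of two bands, after the
#' Lowe ratio test and mutual cross-check.  \code{pairs} columns:
#' \code{idxA}, \code{idxB} (1-based indices into the two [FeatureSet]s) and
#' \code{distance} (descriptor distance).  Each index occurs at most once per
#' side.
#'
#' @slot bandA,bandB integer band indices.
#' @slot pairs data.frame of matches.
#' @export
setClass("PairMatches",
  representation(bandA = "integer", bandB = "integer", pairs = "data.frame"),
  validity = function(object) {
    msgs <- character()
    need <- c("idxA", "idxB", "distance")
    if (!all(need %in% names(object@pairs)))
      msgs <- c(msgs, "pairs must have columns idxA, idxB, distance")
    else {
      if (anyDuplicated(object@pairs$idxA) || anyDuplicated(object@pairs$idxB))
        msgs <- c(msgs, "matching must be one-to-one on each side")
    }
    if (length(msgs)) msgs else TRUE
  })

#' RigidTransform: 2-D rotation + translation
#'
#' Maps a point \code{p = (row, col)} to \code{rotation \%*\% p +
#' translation}.  The rotation matrix is orthonormal with determinant +1 (no
#' scaling or reflection); translations are in pixels.
#'
#' @slot rotation 2x2 numeric rotation matrix.
#' @slot translation numeric length-2 vector (row, col) in px.
#' @seealso [estimateRigid()], [applyTransform()], [composeTransforms()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    msgs <- character()
    R <- object@rotation
    if (!all(dim(R) == c(2L, 2L)))
      msgs <- c(msgs, "rotation must be 2x2")
    else {
      if (max(abs(crossprod(R) - diag(2))) > 1e-6)
        msgs <- c(msgs, "rotation must be orthonormal")
      if (abs(det(R) - 1) > 1e-6)
        msgs <- c(msgs, "rotation must have determinant +1")
    }
    if (length(object@translation) != 2L)
      msgs <- c(msgs, "translation must have length 2")
    if (length(msgs)) msgs else TRUE
  })

#' ChainSet: feature tracks chained around the band loop
#'
#' One chain per seed feature in the first band, following single best
#' matches band 1 -> 2 -> ... -> N -> 1.  \code{featureIndex[r, b]} is the
#' 1-based feature index of chain \code{r} in band \code{b} (NA after the
#' track breaks); the last column holds the band-1 feature the loop returned
#' to.  \code{closureDistance} is the Euclidean distance, in band 1's frame,
#' between the seed point and the loop-returned point (NA for incomplete
#' chains).
#'
#' @slot featureIndex integer matrix, chains x (bands + 1).
#' @slot startCoord,endCoord numeric matrices (row, col) in band 1.
#' @slot closureDistance numeric per chain, px.
#' @slot complete logical per chain.
#' @slot bands integer vector of the band indices the loop traverses.
#' @export
setClass("ChainSet",
  representation(featureIndex = "matrix", startCoord = "matrix",
                 endCoord = "matrix", closureDistance = "numeric",
                 complete = "logical", bands = "integer"),
  validity = function(object) {
    msgs <- character()
    n <- nrow(object@featureIndex)
    if (nrow(object@startCoord) != n || length(object@complete) != n ||
        length(object@closureDistance) != n)
      msgs <- c(msgs, "per-chain slots must have equal lengths")
    bad <- object@complete & !is.na(object@closureDistance) &
      object@closureDistance < 0
    if (any(bad)) msgs <- c(msgs, "closure distances must be >= 0")
    if (any(!object@complete & !is.na(object@closureDistance)))
      msgs <- c(msgs, "closure distance defined only for complete chains")
    if (length(msgs)) msgs else TRUE
  })

#' TransformSet: per-band rigid transforms into a reference frame
#'
#' @slot referenceBand integer; the transform for this band is the identity.
#' @slot transforms list of [RigidTransform], one per band, mapping that
#'   band's coordinates into the reference band's frame.
#' @slot residuals numeric per band: RMS residual of the inlier
#'   correspondences used to estimate the transform (NA where no estimate was
#'   needed or possible).
#' @export
setClass("TransformSet",
  representation(referenceBand = "integer", transforms = "list",
                 residuals = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@transforms) != length(object@residuals))
      msgs <- c(msgs, "one residual per transform required")
    rb <- object@referenceBand
    if (rb < 1L || rb > length(object@transforms))
      msgs <- c(msgs, "referenceBand out of range")
    else {
      tr <- object@transforms[[rb]]
      if (max(abs(tr@rotation - diag(2))) > 1e-9 ||
          max(abs(tr@translation)) > 1e-9)
        msgs <- c(msgs, "reference band transform must be the identity")
    }
    if (length(msgs)) msgs else TRUE
  })

#' PhantomTruth: ground truth for a generated phantom
#'
#' @slot trueTransforms list of [RigidTransform], one per band, mapping that
#'   band's coordinates into the reference (band 1) frame.
#' @slot vesselMask logical matrix: the main-vessel mask in the reference
#'   frame (capillary clutter excluded).
#' @slot abundances numeric matrix (2 x pixels): true per-pixel mixing
#'   weights of the oxy/deoxy end-members, columns summing to 1 on vessel
#'   pixels.
#' @slot spectra numeric matrix (bands x 2): true end-member absorbance
#'   spectra.
#' @slot so2 numeric matrix: the per-pixel true oxygen saturation field.
#' @export
setClass("PhantomTruth",
  representation(trueTransforms = "list", vesselMask = "matrix",
                 abundances = "matrix", spectra = "matrix", so2 = "matrix"),
  validity = function(object) {
    msgs <- character()
    if (!any(object@vesselMask))
      msgs <- c(msgs, "vessel mask must be non-empty")
    if (length(msgs)) msgs else TRUE
  })

#' SO2Map: oxygen-saturation image from dual-wavelength inversion
#'
#' Values are the oxyhemoglobin fraction of total hemoglobin, dimensionless
#' in \code{[0, 1]} after clipping; \code{clipped} and \code{undefined} flag
#' pixels whose raw solution fell outside the range or whose total absorbance
#' was zero.
#'
#' @slot values numeric matrix in \code{[0, 1]} (NA where undefined).
#' @slot lambda1,lambda2 numeric, the two wavelengths (nm) used.
#' @slot clipped logical matrix: raw value outside \code{[0, 1]}.
#' @slot undefined logical matrix: solution undefined (zero absorbance).
#' @export
setClass("SO2Map",
  representation(values = "matrix", lambda1 = "numeric", lambda2 = "numeric",
                 clipped = "matrix", undefined = "matrix"),
  validity = function(object) {
    v <- object@values[!is.na(object@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      "values must be within [0, 1] after clipping" else TRUE
  })

#' UnmixResult: blind end-member extraction output
#'
#' @slot endmembers L x N matrix, end-member spectra as columns (each column
#'   sums to 1: the update operates on sum-normalized spectra).
#' @slot abundances N x pixels matrix, nonnegative, columns summing to 1.
#' @slot rho numeric regularization weight.
#' @slot converged logical.
#' @slot trace numeric vector of reconstruction errors per iteration.
#' @export
setClass("UnmixResult",
  representation(endmembers = "matrix", abundances = "matrix",
                 rho = "numeric", converged = "logical", trace = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (ncol(object@endmembers) != nrow(object@abundances))
      msgs <- c(msgs, "end-member count must match abundance rows")
    A <- object@abundances
    if (length(A)) {
      if (min(A) < -1e-8) msgs <- c(msgs, "abundances must be nonnegative")
      if (max(abs(colSums(A) - 1)) > 1e-6)
        msgs <- c(msgs, "abundance columns must sum to 1")
    }
    if (length(msgs)) msgs else TRUE
  })
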