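#' @rdname HyperCube-class
#' @param data numeric 3-D array, bands x rows x cols.
#' @param wavelengths numeric per-band wavelengths in nm.
#' @param bitDepth integer bit depth of the stored samples.
#' @export
HyperCube <- function(data, wavelengths, bitDepth = 12L) {
  new("HyperCube", data = data, wavelengths = as.numeric(wavelengths),
      bitDepth = as.integer(bitDepth))
}

#' @rdname MaskStack-class
#' @param masks logical 3-D array.
#' @param provenance stage label, \code{"threshold"} or \code{"levelset"}.
#' @export
MaskStack <- function(masks, provenance) {
  new("MaskStack", masks = masks, provenance = provenance)
}

#' @rdname RigidTransform-class
#' @param angle rotation angle in radians (counter-clockwise in the
#'   (row, col) plane); ignored when \code{rotation} is given.
#' @param translation numeric length-2 (row, col) shift in px.
#' @param rotation optional explicit 2x2 rotation matrix.
#' @export
RigidTransform <- function(angle = 0, translation = c(0, 0),
                           rotation = NULL) {
  if (is.null(rotation))
    rotation <- matrix(c(cos(angle), sin(angle),
                         -sin(angle), cos(angle)), 2L, 2L)
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Number of spectral bands
#' @param x a [HyperCube] or [MaskStack].
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))
#' @rdname nBands
#' @export
setMethod("nBands", "HyperCube", function(x) dim(x@data)[1L])
#' @rdname nBands
#' @export
setMethod("nBands", "MaskStack", function(x) dim(x@masks)[1L])

#' Cube intensity data
#' @param x a [HyperCube].
#' @return the bands x rows x cols array.
#' @export
cubeData <- function(x) x@data

#' Per-band wavelengths (nm)
#' @param x a [HyperCube].
#' @export
wavelengths <- function(x) x@wavelengths

#' Bit depth of the stored samples
#' @param x a [HyperCube].
#' @export
bitDepth <- function(x) x@bitDepth

#' Extract one band as a 2-D matrix
#' @param x a [HyperCube] or [MaskStack].
#' @param i band index.
#' @export
setGeneric("getBand", function(x, i) standardGeneric("getBand"))
#' @rdname getBand
#' @export
setMethod("getBand", "HyperCube", function(x, i) x@data[i, , ])
#' @rdname getBand
#' @export
setMethod("getBand", "MaskStack", function(x, i) x@masks[i, , ])

#' Mask array of a MaskStack
#' @param x a [MaskStack].
#' @export
maskData <- function(x) x@masks

#' Keypoint table of a FeatureSet
#' @param x a [FeatureSet].
#' @export
featurePoints <- function(x) x@points

#' Descriptor matrix of a FeatureSet
#' @param x a [FeatureSet].
#' @export
featureDescriptors <- function(x) x@descriptors

#' Number of features / matches / chains
#' @param x object.
#' @export
setMethod("length", "FeatureSet", function(x) nrow(x@points))
#' @rdname length-FeatureSet-method
#' @export
setMethod("length", "PairMatches", function(x) nrow(x@pairs))
#' @rdname length-FeatureSet-method
#' @export
setMethod("length", "ChainSet", function(x) nrow(x@featureIndex))

#' Closure distances of a chain set
#' @param x a [ChainSet].
#' @export
closureDistances <- function(x) x@closureDistance

#' Per-band transforms of a TransformSet
#' @param x a [TransformSet].
#' @export
transforms <- function(x) x@transforms

#' Reference band of a TransformSet
#' @param x a [TransformSet].
#' @export
referenceBand <- function(x) x@referenceBand

setMethod("show", "HyperCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("HyperCube: %d bands x %d x %d px, %d-bit\n",
              d[1L], d[2L], d[3L], object@bitDepth))
  cat(sprintf("  wavelengths: %.1f-%.1f nm\n",
              min(object@wavelengths), max(object@wavelengths)))
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@masks)
  cat(sprintf("MaskStack (%s): %d bands x %d x %d px, %.1f%% foreground\n",
              object@provenance, d[1L], d[2L], d[3L],
              100 * mean(object@masks)))
})

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet (%s): %d keypoints, descriptor length %d\n",
              object@detector, nrow(object@points),
              ncol(object@descriptors)))
})

setMethod("show", "PairMatches", function(object) {
  cat(sprintf("PairMatches: bands %d-%d, %d matches\n",
              object@bandA, object@bandB, nrow(object@pairs)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- atan2(object@rotation[2L, 1L], object@rotation[1L, 1L])
  cat(sprintf("RigidTransform: angle %.4f rad, translation (%.3f, %.3f) px\n",
              ang, object@translation[1L], object@translation[2L]))
})

setMethod("show", "ChainSet", function(object) {
  cat(sprintf(
    "ChainSet: %d chains over %d bands, %d complete, median closure %.2f px\n",
    nrow(object@featureIndex), length(object@bands), sum(object@complete),
    if (any(object@complete))
      median(object@closureDistance[object@complete]) else NA_real_))
})

setMethod("show", "TransformSet", function(object) {
  cat(sprintf("TransformSet: %d bands, reference band %d\n",
              length(object@transforms), object@referenceBand))
})

setMethod("show", "SO2Map", function(object) {
  cat(sprintf(
    "SO2Map: %d x %d px at %g/%g nm; %d clipped, %d undefined\n",
    nrow(object@values), ncol(object@values), object@lambda1,
    object@lambda2, sum(object@clipped), sum(object@undefined)))
})

setMethod("show", "UnmixResult", function(object) {
  cat(sprintf(
    "UnmixResult: %d end-members x %d bands, %d pixels, rho %g, %s\n",
    ncol(object@endmembers), nrow(object@endmembers),
    ncol(object@abundances), object@rho,
    if (object@converged) "converged" else "not converged"))
})
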