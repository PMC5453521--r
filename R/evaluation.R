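# Registration quality metrics: directional errors over matched feature
# tracks, and the spectral-spread analysis of a small on-vessel ROI.

#' Per-band coordinates of a chain set's features
#'
#' @param chains a [ChainSet] (typically the inliers).
#' @param featureSets list of [FeatureSet]s indexed by band.
#' @return list with one n x 2 (row, col) matrix per loop band, aligned
#'   across bands chain-by-chain (the loop-return column is not included).
#' @export
chainCoordinates <- function(chains, featureSets) {
  lapply(seq_along(chains@bands), function(pos) {
    b <- chains@bands[pos]
    idx <- chains@featureIndex[, pos]
    pts <- featureSets[[b]]@points
    cbind(row = pts$row[idx], col = pts$col[idx])
  })
}

#' Directional registration error over feature tracks
#'
#' Measures how much matched features move between consecutive bands, in
#' the column (X) and row (Y) directions.  The \code{"literal"} variant is
#' the mean over bands of the summed squared consecutive-band coordinate
#' differences, \eqn{E_x = \frac{1}{N} \sum_{i} \sum_r (x_i^r -
#' x_{i+1}^r)^2}; the \code{"rms"} variant is the root-mean-square
#' per-feature consecutive-band displacement,
#' \eqn{\sqrt{\frac{1}{(N-1)R} \sum \sum (\Delta x)^2}}, which reads in
#' pixels and is the headline summary.  Both agree on a single-feature
#' two-band input up to these normalizations.
#'
#' @param tracks list of n x 2 (row, col) matrices, one per band, rows
#'   aligned across bands (see [chainCoordinates()]).
#' @param variant \code{"rms"} (default) or \code{"literal"}.
#' @return list with \code{ex}, \code{ey}, \code{n_bands},
#'   \code{n_features}, \code{variant}.
#' @export
directionalError <- function(tracks, variant = c("rms", "literal")) {
  variant <- match.arg(variant)
  N <- length(tracks)
  if (N < 2L) stop("need coordinates for at least two bands")
  R <- nrow(tracks[[1L]])
  if (any(vapply(tracks, nrow, integer(1L)) != R))
    stop("ragged tracks: all bands must carry the same features")
  ssx <- 0; ssy <- 0
  for (i in seq_len(N - 1L)) {
    d <- tracks[[i]] - tracks[[i + 1L]]
    ssy <- ssy + sum(d[, 1L]^2)   # row = Y
    ssx <- ssx + sum(d[, 2L]^2)   # col = X
  }
  if (variant == "literal") {
    ex <- ssx / N; ey <- ssy / N
  } else {
    ex <- sqrt(ssx / ((N - 1L) * R)); ey <- sqrt(ssy / ((N - 1L) * R))
  }
  list(ex = ex, ey = ey, n_bands = N, n_features = R, variant = variant)
}

#' Spectral spread of a square on-vessel ROI
#'
#' Extracts the spectrum of every pixel of a \code{side x side} region and
#' summarizes how concentrated the curves are: the standard deviation
#' across the ROI's pixels at each band, averaged over bands.  Well
#' registered stacks give concentrated (low-spread) curves; band-to-band
#' jitter smears them.
#'
#' @param cube a [HyperCube].
#' @param roi list or vector \code{(row, col, side)}: 0-based top-left
#'   corner and side length in px (side 6 gives the 36-pixel region used
#'   for visual spectra).
#' @return list with \code{roi}, \code{spectra} (side^2 x bands matrix),
#'   \code{per_band_sd} and \code{mean_sd}.
#' @export
spectralSpread <- function(cube, roi) {
  roi <- as.numeric(unlist(roi))
  r0 <- roi[1L]; c0 <- roi[2L]; side <- roi[3L]
  d <- dim(cube@data)
  if (r0 < 0 || c0 < 0 || side < 1 ||
      r0 + side > d[2L] || c0 + side > d[3L])
    stop("ROI out of bounds")
  rows <- (r0 + 1):(r0 + side)
  cols <- (c0 + 1):(c0 + side)
  block <- cube@data[, rows, cols, drop = FALSE]
  spectra <- t(matrix(block, d[1L], side * side))
  perBandSd <- apply(spectra, 2L, stats::sd)
  list(roi = c(row = r0, col = c0, side = side), spectra = spectra,
       per_band_sd = perBandSd, mean_sd = mean(perBandSd))
}

#' Export ROI spectra as a plain-text table
#'
#' One row per ROI pixel, one column per wavelength.
#'
#' @param spread result of [spectralSpread()].
#' @param wavelengths per-band wavelengths for the column names.
#' @param path output TSV path.
#' @export
exportSpectra <- function(spread, wavelengths, path) {
  tab <- as.data.frame(spread$spectra)
  names(tab) <- sprintf("nm%.1f", wavelengths)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
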