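# Per-band vessel extraction: windowed Otsu thresholding gated on the global
# between-class variance, then a curvature-regularized level-set contour
# filter that removes capillary clutter and evens the vessel boundary.

#' Otsu threshold with between-class-variance diagnostics
#'
#' Picks the threshold maximizing the between-class variance
#' \eqn{\sigma_B^2 = \omega_0 \omega_1 (\mu_1 - \mu_0)^2} over all candidate
#' split levels.  For integer-valued input the search is equivalent to an
#' exhaustive scan of every integer level (candidate splits between occupied
#' levels are redundant and resolve to the smaller level); non-integer input
#' is split at its observed values, which makes the partition invariant
#' under positive affine intensity rescaling.  Ties break toward the
#' smallest threshold.  Class 0 is \code{x <= threshold} (the dark class).
#'
#' @param band numeric matrix (or vector) of intensities.
#' @return list with \code{threshold}, \code{sigma_b2}, \code{omega0},
#'   \code{omega1}, \code{mu0}, \code{mu1} and \code{degenerate} (TRUE for a
#'   constant image, where \code{sigma_b2} is 0 and the threshold is the
#'   constant itself).
#' @export
otsuThreshold <- function(band) {
  x <- as.numeric(band)
  if (!length(x)) stop("band must be non-empty")
  u <- sort(unique(x))
  if (length(u) == 1L)
    return(list(threshold = u, sigma_b2 = 0, omega0 = 1, omega1 = 0,
                mu0 = u, mu1 = NaN, degenerate = TRUE))
  n <- length(x)
  cnt <- tabulate(match(x, u), nbins = length(u))
  csum <- cumsum(cnt)
  cmu <- cumsum(cnt * u)
  total <- cmu[length(u)]
  # split after level u[k]: class0 = {x <= u[k]}, k = 1..K-1
  k <- seq_len(length(u) - 1L)
  w0 <- csum[k] / n
  w1 <- 1 - w0
  mu0 <- cmu[k] / csum[k]
  mu1 <- (total - cmu[k]) / (n - csum[k])
  sb2 <- w0 * w1 * (mu1 - mu0)^2
  best <- which.max(sb2)  # which.max returns the first (smallest) maximizer
  list(threshold = u[best], sigma_b2 = sb2[best],
       omega0 = w0[best], omega1 = w1[best],
       mu0 = mu0[best], mu1 = mu1[best], degenerate = FALSE)
}

#' Windowed Otsu segmentation gated on global between-class variance
#'
#' Tiles the band into non-overlapping \code{window x window} windows
#' (row-major; edge tiles keep their residual size).  A window whose pixel
#' variance reaches the gate — the between-class variance of the global Otsu
#' split of the whole band — is binarized with its own Otsu threshold, dark
#' class as vessel foreground; homogeneous windows below the gate become
#' background.  Because both the gate and the window variances scale
#' identically under positive affine intensity changes, the output mask is
#' invariant to per-band global intensity modulation.
#'
#' @param band numeric matrix.
#' @param window window side length in px (default 50).
#' @param gate_fraction fraction of the global between-class variance a
#'   window's variance must reach to be binarized (default 0.1).  A window
#'   crossed by a thin vessel sliver carries the full vessel/background
#'   contrast at low coverage, so its total variance can fall below the
#'   whole band's between-class variance while still holding genuine
#'   structure; pure-noise windows sit orders of magnitude below either
#'   quantity, so a fractional floor separates the two robustly.
#' @return logical matrix, \code{TRUE} = vessel.
#' @export
localThresholdSegment <- function(band, window = 50L, gate_fraction = 0.1) {
  if (window < 2L) stop("window must be >= 2 px")
  nr <- nrow(band); nc <- ncol(band)
  if (window > nr || window > nc)
    stop(sprintf("window (%d) larger than image (%dx%d)", window, nr, nc))
  gate <- gate_fraction * otsuThreshold(band)$sigma_b2
  out <- matrix(FALSE, nr, nc)
  rStarts <- seq(1L, nr, by = window)
  cStarts <- seq(1L, nc, by = window)
  for (r0 in rStarts) {
    r1 <- min(r0 + window - 1L, nr)
    for (c0 in cStarts) {
      c1 <- min(c0 + window - 1L, nc)
      tile <- band[r0:r1, c0:c1]
      v <- mean((tile - mean(tile))^2)   # population variance
      if (v >= gate && gate > 0) {
        ot <- otsuThreshold(tile)
        if (!ot$degenerate)
          out[r0:r1, c0:c1] <- tile <= ot$threshold
      }
    }
  }
  out
}

#' Level-set evolution parameters
#'
#' @param max_iters iteration cap (>= 1).
#' @param smoothing_weight curvature-term weight: the number of
#'   morphological curvature (majority-vote) passes applied per iteration;
#'   0 leaves boundaries untouched.
#' @param convergence_tol stop when the fraction of pixels changed in an
#'   iteration falls below this (in [0, 1)).
#' @param min_component_area connected components smaller than this many
#'   pixels are removed before evolution.
#' @return a list of class parameters consumed by [levelsetFilter()].
#' @export
levelSetParams <- function(max_iters = 50L, smoothing_weight = 1L,
                           convergence_tol = 1e-3,
                           min_component_area = 120L) {
  stopifnot(max_iters >= 1L, smoothing_weight >= 0,
            convergence_tol >= 0, convergence_tol < 1,
            min_component_area >= 0)
  list(max_iters = as.integer(max_iters),
       smoothing_weight = as.integer(smoothing_weight),
       convergence_tol = convergence_tol,
       min_component_area = as.integer(min_component_area))
}

.majority <- function(m) {
  k <- matrix(1, 3L, 3L)
  s <- EBImage::filter2(m, k, boundary = 0)
  (s > 4.5) * 1
}

.removeSmall <- function(mask, minArea) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  if (minArea > 0L) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= minArea)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Level-set contour filter for binary vessel masks
#'
#' Removes connected components below \code{min_component_area}, then
#' evolves the remaining contour under a morphological curvature flow
#' (majority-vote regularization, the discrete counterpart of
#' mean-curvature motion) initialized from the thresholded mask, until the
#' per-iteration fraction of changed pixels drops below
#' \code{convergence_tol} or \code{max_iters} is reached.  Each retained
#' component stays one contiguous region: if curvature flow pinches a
#' component apart, only its largest piece is kept, so the component count
#' never increases.
#'
#' @param mask logical matrix, \code{TRUE} = vessel.
#' @param params a [levelSetParams()] list.
#' @return list-free logical matrix of the filtered mask; the number of
#'   iterations used is attached as attribute \code{"iterations"}.
#' @export
levelsetFilter <- function(mask, params = levelSetParams()) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE
  if (!any(mask)) {
    attr(mask, "iterations") <- 0L
    return(mask)
  }
  phi <- 1 * .removeSmall(mask, params$min_component_area)
  nInit <- max(EBImage::bwlabel(phi))
  iters <- 0L
  if (params$smoothing_weight > 0L) {
    npix <- length(phi)
    for (it in seq_len(params$max_iters)) {
      newPhi <- phi
      for (s in seq_len(params$smoothing_weight))
        newPhi <- .majority(newPhi)
      changed <- sum(newPhi != phi) / npix
      phi <- newPhi
      iters <- it
      if (changed < params$convergence_tol) break
    }
  }
  out <- phi > 0.5
  # contiguity guarantee: one piece per surviving component
  if (any(out)) {
    lab <- EBImage::bwlabel(out)
    nOut <- max(lab)
    if (nOut > nInit) {
      sizes <- tabulate(lab[lab > 0])
      keep <- order(sizes, decreasing = TRUE)[seq_len(nInit)]
      out <- matrix(lab %in% keep, nrow(out), ncol(out))
    }
    out <- .removeSmall(out, params$min_component_area)
  }
  attr(out, "iterations") <- iters
  out
}

#' Segment every band of a cube into vessel masks
#'
#' Applies [localThresholdSegment()] then [levelsetFilter()] independently
#' per band.  Constant (degenerate) bands yield all-background masks and are
#' flagged in the log.
#'
#' @param cube a [HyperCube].
#' @param window Otsu window side length in px.
#' @param params a [levelSetParams()] list.
#' @param logfile optional path; when given, a plain-text (TSV) log with
#'   per-band global threshold, gate variance, level-set iterations and the
#'   degenerate flag is written there.
#' @return a [MaskStack] with provenance \code{"levelset"}.
#' @export
segmentCube <- function(cube, window = 50L, params = levelSetParams(),
                        logfile = NULL) {
  validObject(cube)
  nb <- nBands(cube)
  d <- dim(cube@data)
  masks <- array(FALSE, d)
  log <- data.frame(band = seq_len(nb), threshold = NA_real_,
                    sigma_b2 = NA_real_, iterations = 0L,
                    degenerate = FALSE)
  for (b in seq_len(nb)) {
    band <- getBand(cube, b)
    ot <- otsuThreshold(band)
    log$threshold[b] <- ot$threshold
    log$sigma_b2[b] <- ot$sigma_b2
    if (ot$degenerate) {
      log$degenerate[b] <- TRUE
      next
    }
    m <- levelsetFilter(localThresholdSegment(band, window), params)
    log$iterations[b] <- attr(m, "iterations")
    masks[b, , ] <- m
  }
  if (!is.null(logfile))
    utils::write.table(log, logfile, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  MaskStack(masks, "levelset")
}
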