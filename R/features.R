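# Scale- and rotation-invariant interest points on binary vessel masks.
# The detector contract is pluggable by name; the built-in "hessian"
# detector is a multiscale determinant-of-Hessian blob detector with
# SURF-style oriented gradient-histogram descriptors, which is what the
# registration stage needs from a SURF-family detector: repeatable
# sub-pixel keypoints with descriptors that survive small rigid motion.

.detectorRegistry <- new.env(parent = emptyenv())

#' Register a feature detector implementation
#'
#' Any function \code{f(mask, ...)} returning a [FeatureSet] can be
#' registered and selected by name in [detectFeatures()].
#'
#' @param name detector name.
#' @param fun detector function.
#' @export
registerDetector <- function(name, fun) {
  assign(name, fun, envir = .detectorRegistry)
  invisible(name)
}

#' List registered detector names
#' @export
listDetectors <- function() ls(.detectorRegistry)

#' Detect interest points on a binary mask
#'
#' Runs the named detector on the mask (converted to an 8-bit-style
#' \{0, 1\} gray image, since interest-point detectors assume gray-scale
#' input).  Deterministic for fixed input and settings.  An empty
#' foreground yields an empty feature set with a warning.
#'
#' @param mask logical matrix, \code{TRUE} = vessel.
#' @param detector registered detector name (default \code{"hessian"}).
#' @param ... passed to the detector implementation.
#' @return a [FeatureSet].
#' @export
detectFeatures <- function(mask, detector = "hessian", ...) {
  stopifnot(is.matrix(mask), length(mask) > 0)
  if (!exists(detector, envir = .detectorRegistry))
    stop("unknown detector '", detector, "'; registered: ",
         paste(listDetectors(), collapse = ", "))
  if (!any(mask)) {
    warning("empty foreground: no features to detect")
    return(emptyFeatureSet(detector))
  }
  fun <- get(detector, envir = .detectorRegistry)
  fun(mask, ...)
}

emptyFeatureSet <- function(detector, descLen = 64L) {
  new("FeatureSet",
      points = data.frame(row = numeric(), col = numeric(),
                          scale = numeric(), orientation = numeric(),
                          response = numeric()),
      descriptors = matrix(numeric(), 0L, descLen),
      detector = detector)
}

.gradients <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  dr <- matrix(0, nr, nc); dc <- matrix(0, nr, nc)
  dr[2:(nr - 1), ] <- (g[3:nr, ] - g[1:(nr - 2), ]) / 2
  dc[, 2:(nc - 1)] <- (g[, 3:nc] - g[, 1:(nc - 2)]) / 2
  list(dr = dr, dc = dc)
}

# Multiscale determinant-of-Hessian keypoints with oriented descriptors.
hessianDetect <- function(mask, scales = c(2, 3, 4.5, 6.5),
                          threshold_rel = 0.02, max_features = 200L) {
  img <- 1 * mask
  nr <- nrow(img); nc <- ncol(img)
  smooth <- vector("list", length(scales))
  resp <- array(0, c(length(scales), nr, nc))
  for (si in seq_along(scales)) {
    s <- scales[si]
    g <- EBImage::gblur(img, sigma = s)
    smooth[[si]] <- g
    drr <- matrix(0, nr, nc); dcc <- matrix(0, nr, nc)
    drc <- matrix(0, nr, nc)
    drr[2:(nr - 1), ] <- g[3:nr, ] + g[1:(nr - 2), ] - 2 * g[2:(nr - 1), ]
    dcc[, 2:(nc - 1)] <- g[, 3:nc] + g[, 1:(nc - 2)] - 2 * g[, 2:(nc - 1)]
    gr <- .gradients(g)$dr
    drc[, 2:(nc - 1)] <- (gr[, 3:nc] - gr[, 1:(nc - 2)]) / 2
    resp[si, , ] <- s^4 * (drr * dcc - drc^2)
  }
  thr <- threshold_rel * max(resp)
  if (thr <= 0) return(emptyFeatureSet("hessian"))
  pts <- NULL
  for (si in seq_along(scales)) {
    R <- resp[si, , ]
    # 3x3 spatial non-max suppression (border excluded)
    cand <- which(R > thr, arr.ind = TRUE)
    cand <- cand[cand[, 1L] > 2 & cand[, 1L] < nr - 1 &
                 cand[, 2L] > 2 & cand[, 2L] < nc - 1, , drop = FALSE]
    if (!nrow(cand)) next
    keep <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      v <- R[r, c]
      nb <- R[(r - 1):(r + 1), (c - 1):(c + 1)]
      if (v < max(nb)) return(FALSE)
      if (v == max(nb) && sum(nb == v) > 1L &&
          which(nb == v)[1L] != 5L) return(FALSE)  # deterministic tie-break
      if (si > 1L && resp[si - 1L, r, c] > v) return(FALSE)
      if (si < length(scales) && resp[si + 1L, r, c] >= v &&
          resp[si + 1L, r, c] != v) return(FALSE)
      TRUE
    }, logical(1L))
    cand <- cand[keep, , drop = FALSE]
    if (!nrow(cand)) next
    # sub-pixel refinement by 2-D quadratic fit
    sub <- t(vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      gr <- c((R[r + 1, c] - R[r - 1, c]) / 2, (R[r, c + 1] - R[r, c - 1]) / 2)
      hrr <- R[r + 1, c] + R[r - 1, c] - 2 * R[r, c]
      hcc <- R[r, c + 1] + R[r, c - 1] - 2 * R[r, c]
      hrc <- (R[r + 1, c + 1] - R[r + 1, c - 1] -
              R[r - 1, c + 1] + R[r - 1, c - 1]) / 4
      H <- matrix(c(hrr, hrc, hrc, hcc), 2L)
      off <- c(0, 0)
      if (abs(det(H)) > 1e-12) {
        off <- as.numeric(-solve(H, gr))
        off <- pmin(pmax(off, -0.5), 0.5)
      }
      c(r - 1 + off[1L], c - 1 + off[2L], R[r, c])
    }, numeric(3L)))
    pts <- rbind(pts, cbind(sub, scales[si], si))
  }
  if (is.null(pts) || !nrow(pts)) return(emptyFeatureSet("hessian"))
  colnames(pts) <- c("row", "col", "response", "scale", "si")
  ord <- order(-pts[, "response"], pts[, "row"], pts[, "col"])
  pts <- pts[ord, , drop = FALSE]
  if (nrow(pts) > max_features) pts <- pts[seq_len(max_features), , drop = FALSE]
  orientation <- numeric(nrow(pts))
  desc <- matrix(0, nrow(pts), 64L)
  grads <- lapply(smooth, .gradients)
  for (i in seq_len(nrow(pts))) {
    si <- pts[i, "si"]
    s <- pts[i, "scale"]
    g <- grads[[si]]
    orientation[i] <- .dominantOrientation(g, pts[i, "row"], pts[i, "col"], s)
    desc[i, ] <- .surfDescriptor(g, pts[i, "row"], pts[i, "col"], s,
                                 orientation[i])
  }
  new("FeatureSet",
      points = data.frame(row = pts[, "row"], col = pts[, "col"],
                          scale = pts[, "scale"], orientation = orientation,
                          response = pts[, "response"]),
      descriptors = desc, detector = "hessian")
}

# Dominant gradient orientation in a Gaussian-weighted disc of radius 6s.
.dominantOrientation <- function(g, r, c, s, nbins = 36L) {
  rad <- 6 * s
  off <- seq(-rad, rad, by = max(1, s / 2))
  grid <- expand.grid(dr = off, dc = off)
  d2 <- grid$dr^2 + grid$dc^2
  grid <- grid[d2 <= rad^2, ]
  w <- exp(-(grid$dr^2 + grid$dc^2) / (2 * (2.5 * s)^2))
  gr <- sampleImage(g$dr, r + grid$dr, c + grid$dc, "bilinear", 0)
  gc <- sampleImage(g$dc, r + grid$dr, c + grid$dc, "bilinear", 0)
  mag <- sqrt(gr^2 + gc^2) * w
  ang <- atan2(gr, gc)  # angle measured from +col axis toward +row
  bin <- (floor((ang + pi) / (2 * pi) * nbins)) %% nbins + 1L
  h <- vapply(seq_len(nbins), function(b) sum(mag[bin == b]), numeric(1L))
  # circular smoothing
  hs <- (h + c(tail(h, 1L), head(h, -1L)) + c(tail(h, -1L), head(h, 1L))) / 3
  b <- which.max(hs)
  # parabolic refinement around the peak bin center
  bl <- if (b == 1L) nbins else b - 1L
  br <- if (b == nbins) 1L else b + 1L
  denom <- hs[bl] - 2 * hs[b] + hs[br]
  delta <- if (abs(denom) > 1e-12) 0.5 * (hs[bl] - hs[br]) / denom else 0
  (-pi + (b - 0.5 + delta) * 2 * pi / nbins)
}

# SURF-style descriptor: 12x12 sample grid (spacing s) rotated into the
# keypoint frame, gradients rotated likewise, pooled into 4x4 cells of
# (sum dx, sum dy, sum |dx|, sum |dy|), L2-normalized.
.surfDescriptor <- function(g, r, c, s, theta) {
  n <- 12L
  idx <- seq_len(n) - (n + 1) / 2   # -5.5 .. 5.5
  grid <- expand.grid(gr = idx, gc = idx)
  ct <- cos(theta); st <- sin(theta)
  # rotate sample offsets into image frame ((row, col); theta from +col axis)
  dr <- s * (grid$gr * ct + grid$gc * st)
  dc <- s * (-grid$gr * st + grid$gc * ct)
  w <- exp(-(grid$gr^2 + grid$gc^2) / (2 * 3.3^2))
  vr <- sampleImage(g$dr, r + dr, c + dc, "bilinear", 0)
  vc <- sampleImage(g$dc, r + dr, c + dc, "bilinear", 0)
  # rotate gradients into keypoint frame
  fr <- (vr * ct - vc * st) * w
  fc <- (vr * st + vc * ct) * w
  cell <- (ceiling(seq_len(n) / 3))
  cellId <- (cell[match(grid$gr, idx)] - 1L) * 4L + cell[match(grid$gc, idx)]
  d <- numeric(64L)
  for (k in seq_len(16L)) {
    sel <- cellId == k
    d[(k - 1L) * 4L + 1:4] <- c(sum(fr[sel]), sum(fc[sel]),
                                sum(abs(fr[sel])), sum(abs(fc[sel])))
  }
  nrm <- sqrt(sum(d^2))
  if (nrm > 1e-12) d / nrm else d
}

registerDetector("hessian", hessianDetect)

#' Match features between two bands
#'
#' Nearest-neighbor descriptor matching with a Lowe-style ratio test and
#' mutual-best cross-check; the result is one-to-one and symmetric under
#' swapping the two sides.
#'
#' @param featuresA,featuresB [FeatureSet]s (may be empty).
#' @param ratio Lowe ratio threshold (default 0.8).
#' @param bandA,bandB band indices recorded in the result.
#' @return a [PairMatches].
#' @export
matchAdjacent <- function(featuresA, featuresB, ratio = 0.8,
                          bandA = 1L, bandB = 2L) {
  na <- length(featuresA); nb <- length(featuresB)
  empty <- data.frame(idxA = integer(), idxB = integer(),
                      distance = numeric())
  if (na == 0L || nb == 0L)
    return(new("PairMatches", bandA = as.integer(bandA),
               bandB = as.integer(bandB), pairs = empty))
  A <- featuresA@descriptors; B <- featuresB@descriptors
  # squared euclidean distance matrix
  D2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  bestAB <- apply(D, 1L, which.min)
  bestBA <- apply(D, 2L, which.min)
  passRatio <- function(dvec, best) {
    if (length(dvec) < 2L) return(TRUE)
    d1 <- dvec[best]
    d2 <- min(dvec[-best])
    if (d2 <= 0) return(FALSE)  # an equally perfect rival: ambiguous
    d1 <= ratio * d2
  }
  keep <- logical(na)
  for (i in seq_len(na)) {
    j <- bestAB[i]
    if (bestBA[j] != i) next
    if (!passRatio(D[i, ], j)) next
    if (!passRatio(D[, j], i)) next
    keep[i] <- TRUE
  }
  idxA <- which(keep)
  pairs <- data.frame(idxA = idxA, idxB = as.integer(bestAB[idxA]),
                      distance = D[cbind(idxA, bestAB[idxA])])
  new("PairMatches", bandA = as.integer(bandA), bandB = as.integer(bandB),
      pairs = pairs)
}

#' Export a feature set as a plain-text table
#'
#' @param features a [FeatureSet].
#' @param path output path (TSV: row, col, scale, orientation, response,
#'   then descriptor columns).
#' @param band band index written in the first column.
#' @export
exportFeatures <- function(features, path, band = 1L) {
  tab <- cbind(band = band, features@points,
               as.data.frame(features@descriptors))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
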