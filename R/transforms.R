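# Rigid 2-D geometry helpers.  Convention, fixed package-wide: coordinates
# are 0-based (row, col) with pixel centers at integer positions; a
# RigidTransform maps p to rotation %*% p + translation.

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform].
#' @param points numeric n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
applyTransform <- function(transform, points) {
  points <- rbind2mat(points)
  sweep(points %*% t(transform@rotation), 2L, transform@translation, "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform applying \code{inner} first, then \code{outer}.
#' @param outer,inner [RigidTransform]s.
#' @export
composeTransforms <- function(outer, inner) {
  new("RigidTransform",
      rotation = outer@rotation %*% inner@rotation,
      translation = as.numeric(outer@rotation %*% inner@translation) +
        outer@translation)
}

#' Invert a rigid transform
#' @param transform a [RigidTransform].
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% transform@translation))
}

#' Rotation angle of a rigid transform
#' @param transform a [RigidTransform].
#' @return angle in radians.
#' @export
transformAngle <- function(transform) {
  atan2(transform@rotation[2L, 1L], transform@rotation[1L, 1L])
}

rbind2mat <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  points
}

#' Resample an image under a rigid transform
#'
#' Produces the image of \code{img} in the transformed frame: output pixel
#' \code{q} (0-based row, col) takes the value of \code{img} at
#' \code{transform^-1(q)}, so features at position \code{p} in \code{img}
#' appear at \code{transform(p)} in the output.
#'
#' @param img numeric matrix.
#' @param transform a [RigidTransform] (maps input coords to output coords).
#' @param interpolation \code{"bilinear"} or \code{"nearest"}.
#' @param fill value for samples falling outside \code{img}.
#' @return numeric matrix of the same size as \code{img}.
#' @export
warpImage <- function(img, transform, interpolation = c("bilinear", "nearest"),
                      fill = 0) {
  interpolation <- match.arg(interpolation)
  nr <- nrow(img); nc <- ncol(img)
  inv <- invertTransform(transform)
  grid <- cbind(rep(seq_len(nr) - 1, times = nc),
                rep(seq_len(nc) - 1, each = nr))
  src <- applyTransform(inv, grid)
  out <- sampleImage(img, src[, 1L], src[, 2L], interpolation, fill)
  matrix(out, nr, nc)
}

# Sample img (matrix, 0-based coords) at fractional (r, c) positions.
sampleImage <- function(img, r, c, interpolation = "bilinear", fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  if (interpolation == "nearest") {
    ri <- round(r); ci <- round(c)
    ok <- ri >= 0 & ri <= nr - 1 & ci >= 0 & ci <= nc - 1
    out <- rep(fill, length(r))
    out[ok] <- img[cbind(ri[ok] + 1, ci[ok] + 1)]
    return(out)
  }
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 0 & r0 <= nr - 2 & c0 >= 0 & c0 <= nc - 2
  # edge rows/cols where the sample sits exactly on the last pixel
  edge <- (!ok) & r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1
  out <- rep(as.numeric(fill), length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok] + 1, c0[ok] + 1)
    i10 <- cbind(r0[ok] + 2, c0[ok] + 1)
    i01 <- cbind(r0[ok] + 1, c0[ok] + 2)
    i11 <- cbind(r0[ok] + 2, c0[ok] + 2)
    f_r <- fr[ok]; f_c <- fc[ok]
    out[ok] <- img[i00] * (1 - f_r) * (1 - f_c) +
      img[i10] * f_r * (1 - f_c) +
      img[i01] * (1 - f_r) * f_c +
      img[i11] * f_r * f_c
  }
  if (any(edge)) {
    ri <- pmin(pmax(round(r[edge]), 0), nr - 1)
    ci <- pmin(pmax(round(c[edge]), 0), nc - 1)
    out[edge] <- img[cbind(ri + 1, ci + 1)]
  }
  out
}
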