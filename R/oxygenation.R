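# Blood-oxygen-saturation mapping on a registered cube: dual-wavelength
# Beer-Lambert inversion with tabulated extinction coefficients, and blind
# end-member extraction with simplex-constrained abundances for the case
# where the coefficients are unknown.

#' Extinction-coefficient table
#'
#' @param wavelengths nm.
#' @param eps_o2hb,eps_hhb molar extinction coefficients of oxy- and
#'   deoxyhemoglobin at those wavelengths (all > 0, same length).
#' @return a validated list.
#' @export
extinctionTable <- function(wavelengths, eps_o2hb, eps_hhb) {
  stopifnot(length(wavelengths) == length(eps_o2hb),
            length(wavelengths) == length(eps_hhb),
            all(eps_o2hb > 0), all(eps_hhb > 0))
  list(wavelengths = as.numeric(wavelengths),
       eps_o2hb = as.numeric(eps_o2hb), eps_hhb = as.numeric(eps_hhb))
}

#' Approximate hemoglobin extinction coefficients, 550-1000 nm
#'
#' A small tabulation (cm^-1 M^-1) of oxy- and deoxyhemoglobin molar
#' extinction coefficients, linearly interpolated between widely reproduced
#' literature anchor points.  Shipped for convenience; the values are
#' approximate and quantitative work should supply its own table.
#'
#' @return an [extinctionTable()].
#' @export
hemoglobinExtinction <- function() {
  extinctionTable(
    wavelengths = c(550, 560, 570, 576, 580, 590, 600, 620, 650, 680,
                    700, 730, 760, 780, 800, 850, 900, 950, 1000),
    eps_o2hb = c(43016, 32613, 44496, 55540, 50104, 14677, 3200, 942,
                 368, 290, 290, 390, 586, 710, 816, 1058, 1198, 1204,
                 1080),
    eps_hhb = c(53412, 53788, 45072, 38440, 37020, 26810, 14677, 6510,
                3750, 2407, 1794, 1102, 1548, 1096, 762, 691, 761, 717,
                680))
}

#' Interpolate an extinction table onto a wavelength grid
#'
#' Linear interpolation within the table's range (rule-2 clamped at the
#' ends).
#'
#' @param table an [extinctionTable()].
#' @param wavelengths target grid in nm.
#' @return an [extinctionTable()] on \code{wavelengths}.
#' @export
interpolateExtinction <- function(table, wavelengths) {
  extinctionTable(
    wavelengths,
    stats::approx(table$wavelengths, table$eps_o2hb, wavelengths,
                  rule = 2)$y,
    stats::approx(table$wavelengths, table$eps_hhb, wavelengths,
                  rule = 2)$y)
}

.epsAt <- function(table, lambda, tol = 1e-6) {
  i <- which(abs(table$wavelengths - lambda) < tol)
  if (!length(i))
    stop("wavelength ", lambda, " nm not present in the extinction table")
  c(o2hb = table$eps_o2hb[i[1L]], hhb = table$eps_hhb[i[1L]])
}

#' Absorbance cube from transmitted intensities
#'
#' Decadic absorbance \eqn{\Delta A = -\log_{10}(I / I_{ref})} per pixel
#' and band.  Non-positive intensities are floored to one quantization step
#' before the log; the number of floored pixels is attached as attribute
#' \code{"floored"}.
#'
#' @param cube a [HyperCube] of transmitted intensities.
#' @param reference per-band background (incident) intensity, all > 0;
#'   recycled if length 1.
#' @return numeric array (bands x rows x cols) of absorbances, with
#'   attribute \code{"floored"}.
#' @export
absorbance <- function(cube, reference) {
  nb <- nBands(cube)
  if (length(reference) == 1L) reference <- rep(reference, nb)
  if (length(reference) != nb)
    stop("reference must supply one intensity per band")
  if (any(reference <= 0)) stop("reference intensities must be > 0")
  vals <- cube@data
  floored <- sum(vals <= 0)
  vals[vals <= 0] <- 1
  out <- -log10(sweep(vals, 1L, reference, "/"))
  attr(out, "floored") <- floored
  out
}

#' Oxygen saturation by dual-wavelength Beer-Lambert inversion
#'
#' Solves the two-wavelength Beer-Lambert system
#' \eqn{\Delta A^{\lambda} = \epsilon_{O_2Hb}^{\lambda} C_{O_2Hb} +
#' \epsilon_{HHb}^{\lambda} C_{HHb}} (path length folded into the
#' concentrations) for the concentration ratio and returns
#' \eqn{SO_2 = C_{O_2Hb} / (C_{O_2Hb} + C_{HHb})}.  When \eqn{\lambda_1} is
#' an isosbestic point the result depends on the absorbances only through
#' their ratio.  Values outside [0, 1] are clipped and flagged; pixels with
#' zero total concentration are flagged undefined and returned NA.
#'
#' @param absorbance1,absorbance2 2-D absorbance arrays at
#'   \code{lambda1}, \code{lambda2}.
#' @param table an [extinctionTable()].
#' @param lambda1,lambda2 the two wavelengths in nm (must be in the table;
#'   \code{lambda2} must not be isosbestic).
#' @return an [SO2Map].
#' @export
so2DualWavelength <- function(absorbance1, absorbance2, table,
                              lambda1, lambda2) {
  e1 <- .epsAt(table, lambda1)
  e2 <- .epsAt(table, lambda2)
  if (abs(e2["o2hb"] - e2["hhb"]) < 1e-12 * max(e2))
    stop("lambda2 is isosbestic: the system is degenerate")
  det <- e1["o2hb"] * e2["hhb"] - e1["hhb"] * e2["o2hb"]
  if (abs(det) < 1e-12 * max(e1) * max(e2))
    stop("extinction coefficients are linearly dependent at these wavelengths")
  cO <- (absorbance1 * e2["hhb"] - absorbance2 * e1["hhb"]) / det
  cH <- (e1["o2hb"] * absorbance2 - e2["o2hb"] * absorbance1) / det
  tot <- cO + cH
  undefined <- abs(tot) < 1e-300
  raw <- cO / tot
  raw[undefined] <- NA_real_
  clipped <- !undefined & (raw < 0 | raw > 1)
  vals <- pmin(pmax(raw, 0), 1)
  new("SO2Map", values = vals, lambda1 = lambda1, lambda2 = lambda2,
      clipped = clipped & TRUE, undefined = undefined & TRUE)
}

#' Pixelwise ratio of two bands
#'
#' @param cube a [HyperCube].
#' @param bandA,bandB band indices (numerator, denominator).
#' @return numeric matrix of ratios; zero-denominator pixels are NA, their
#'   count attached as attribute \code{"zero_denominator"}.
#' @export
ratioImage <- function(cube, bandA, bandB) {
  nb <- nBands(cube)
  if (bandA < 1L || bandA > nb || bandB < 1L || bandB > nb)
    stop("band index out of range")
  if (bandA == bandB)
    warning("identical band indices: ratio is identically 1")
  num <- getBand(cube, bandA)
  den <- getBand(cube, bandB)
  out <- num / den
  zero <- den == 0
  out[zero] <- NA_real_
  attr(out, "zero_denominator") <- sum(zero)
  out
}

#' Flatten a cube into a bands x pixels data matrix
#'
#' Pixels are ordered column-major (standard R matrix linearization), the
#' order [abundanceMaps()] reverses.
#'
#' @param cube a [HyperCube].
#' @return numeric L x pixels matrix.
#' @export
cubeToMatrix <- function(cube) {
  d <- dim(cube@data)
  matrix(cube@data, d[1L], d[2L] * d[3L])
}

# Exact simplex-constrained least squares, min ||y - P a||, a >= 0,
# sum(a) = 1, solved for all pixels at once by enumerating active
# supports (N is small).  The feasible support solution with the lowest
# objective is the global optimum.
simplexLS <- function(P, Y) {
  N <- ncol(P); npix <- ncol(Y)
  bestObj <- rep(Inf, npix)
  A <- matrix(0, N, npix)
  supports <- lapply(seq_len(2^N - 1L), function(m)
    which(bitwAnd(m, bitwShiftL(1L, seq_len(N) - 1L)) > 0L))
  G <- crossprod(P)
  for (S in supports) {
    k <- length(S)
    K <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    Ki <- tryCatch(solve(K), error = function(e) NULL)
    if (is.null(Ki)) next
    rhs <- rbind(2 * crossprod(P[, S, drop = FALSE], Y), rep(1, npix))
    sol <- Ki %*% rhs
    aS <- sol[seq_len(k), , drop = FALSE]
    feas <- colSums(aS < -1e-10) == 0L
    if (!any(feas)) next
    aS[aS < 0] <- 0
    recon <- P[, S, drop = FALSE] %*% aS
    obj <- colSums((Y - recon)^2)
    upd <- feas & obj < bestObj - 1e-15
    if (any(upd)) {
      bestObj[upd] <- obj[upd]
      A[, upd] <- 0
      A[S, upd] <- aS[, upd]
    }
  }
  A
}

# Deterministic purity-style initialization: the first pick is the pixel
# farthest from the data mean, and each subsequent pick is the pixel
# farthest from the affine hull of the picks so far (for one pick that
# hull is the point itself, for two the line through them, and so on), so
# the initial simplex sits on the extreme pixels of the data cloud.
.purityInit <- function(Y, N) {
  P0 <- matrix(0, nrow(Y), N)
  mu <- rowMeans(Y)
  P0[, 1L] <- Y[, which.max(colSums((Y - mu)^2))]
  if (N > 1L) for (k in 2:N) {
    R <- Y - P0[, 1L]
    if (k > 2L) {
      B <- P0[, 2:(k - 1L), drop = FALSE] - P0[, 1L]
      Q <- qr.Q(qr(B))
      R <- R - Q %*% crossprod(Q, R)
    }
    P0[, k] <- Y[, which.max(colSums(R^2))]
  }
  P0
}

#' Blind end-member extraction with simplex-constrained abundances
#'
#' Alternates (a) exact simplex-constrained least-squares abundance
#' estimation given the current end-members and (b) the regularized
#' closed-form end-member update
#' \deqn{P = (I_L - \tfrac{1}{L} 1_L 1_L^T) Y A^T (A A^T + \rho O)^{-1} +
#' \tfrac{1}{L} 1_L 1_N^T, \quad O = N I_N - 1_N 1_N^T,}
#' which at \eqn{\rho = 0} is the least-squares end-member solution under
#' the constraint that each end-member spectrum sums to 1 (the data columns
#' are sum-normalized internally to match), so each full iteration weakly
#' decreases the reconstruction error.  Stops when the relative change of
#' the reconstruction error falls below \code{tol} or after
#' \code{max_iters} iterations.
#'
#' @param y L x pixels data matrix (L bands, one spectrum per column).
#' @param n_endmembers N, with \code{2 <= N <= L} and at least N pixels.
#' @param rho regularization weight (>= 0).
#' @param max_iters,tol iteration cap and relative-change tolerance.
#' @param init \code{"purity"} (deterministic extreme-projection pixels) or
#'   an explicit L x N matrix of initial end-members.
#' @return an [UnmixResult].
#' @export
extractEndmembers <- function(y, n_endmembers, rho = 0, max_iters = 100L,
                              tol = 1e-10, init = "purity") {
  L <- nrow(y); npix <- ncol(y)
  N <- as.integer(n_endmembers)
  stopifnot(L >= N, N >= 1L, npix >= N, rho >= 0)
  scale <- colSums(y)
  if (any(scale <= 0)) stop("pixel spectra must have positive total signal")
  Y <- sweep(y, 2L, scale, "/")
  P <- if (is.matrix(init)) {
    stopifnot(nrow(init) == L, ncol(init) == N)
    sweep(init, 2L, colSums(init), "/")
  } else .purityInit(Y, N)
  O <- N * diag(N) - matrix(1, N, N)
  C <- diag(L) - matrix(1 / L, L, L)
  trace <- numeric(0)
  converged <- FALSE
  A <- NULL
  for (it in seq_len(max_iters)) {
    A <- if (N == 1L) matrix(1, 1L, npix) else simplexLS(P, Y)
    M <- tcrossprod(A) + rho * O
    Minv <- tryCatch(solve(M), error = function(e) NULL)
    if (is.null(Minv)) {
      warning("singular abundance Gram matrix; adding ridge regularization")
      Minv <- solve(M + 1e-8 * diag(N))
    }
    P <- C %*% Y %*% t(A) %*% Minv + matrix(1 / L, L, N)
    err <- sqrt(sum((Y - P %*% A)^2))
    trace <- c(trace, err)
    # absolute floor: at machine-level error the relative change of the
    # residual is pure rounding noise and never settles
    if (err <= tol * sqrt(sum(Y^2))) {
      converged <- TRUE
      break
    }
    if (it > 1L) {
      prev <- trace[it - 1L]
      if (abs(prev - err) <= tol * max(prev, 1e-300)) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("end-member extraction did not converge in ", max_iters,
            " iterations")
  A <- if (N == 1L) matrix(1, 1L, npix) else simplexLS(P, Y)
  new("UnmixResult", endmembers = P, abundances = A, rho = rho,
      converged = converged, trace = trace)
}

#' Reshape abundances into per-end-member images
#'
#' @param result an [UnmixResult] whose pixels came from [cubeToMatrix()]
#'   (column-major order).
#' @param shape integer (rows, cols); \code{rows * cols} must equal the
#'   pixel count.
#' @return list of N numeric matrices, one abundance map per end-member.
#' @export
abundanceMaps <- function(result, shape) {
  rows <- shape[1L]; cols <- shape[2L]
  if (rows * cols != ncol(result@abundances))
    stop("shape mismatch: ", rows, "x", cols, " != ",
         ncol(result@abundances), " pixels")
  lapply(seq_len(nrow(result@abundances)), function(k)
    matrix(result@abundances[k, ], rows, cols))
}
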