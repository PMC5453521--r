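.synthTable <- function() {
  extinctionTable(c(560, 573, 680, 800),
                  eps_o2hb = c(8.3, 9.5, 1.2, 2.1),
                  eps_hhb = c(11.0, 9.5, 4.4, 1.9))
}

test_that("extinction interpolation is linear inside, clamped outside", {
  tab <- .synthTable()
  it <- interpolateExtinction(tab, c(550, 573, 626.5, 900))
  expect_equal(it$eps_o2hb[2L], 9.5)
  # midpoint of 573 and 680
  expect_equal(it$eps_o2hb[3L], (9.5 + 1.2) / 2)
  # rule-2 clamping at both ends
  expect_equal(it$eps_o2hb[1L], 8.3)
  expect_equal(it$eps_hhb[4L], 1.9)
})

test_that("the built-in hemoglobin table covers the camera range", {
  tab <- hemoglobinExtinction()
  expect_lte(min(tab$wavelength), 550)
  expect_gte(max(tab$wavelength), 1000)
  expect_true(all(tab$eps_o2hb > 0))
  expect_true(all(tab$eps_hhb > 0))
})

test_that("absorbance follows the decadic Beer-Lambert definition", {
  d <- array(0, c(2, 2, 2))
  d[1, , ] <- 100                      # equals reference -> A = 0
  d[2, , ] <- 10                       # one tenth -> A = 1
  cube <- HyperCube(d, c(550, 600), 12L)
  ab <- absorbance(cube, c(100, 100))
  expect_equal(as.numeric(ab[1, , ]), rep(0, 4))
  expect_equal(as.numeric(ab[2, , ]), rep(1, 4))
})

test_that("non-positive intensities are floored and flagged", {
  d <- array(c(0, 50, 100, 100, 100, 100, 100, 100), c(2, 2, 2))
  cube <- HyperCube(d, c(550, 600), 12L)
  ab <- absorbance(cube, c(100, 100))
  expect_true(attr(ab, "floored") > 0)
  expect_true(all(is.finite(ab)))
})

test_that("pure oxyhemoglobin gives SO2 = 1 and a 50/50 mix gives 0.5", {
  tab <- .synthTable()
  # forward Beer's law at lambda1 = 573 (isosbestic), lambda2 = 680
  cO <- 1.3; cH <- 0
  A1 <- cO * 9.5 + cH * 9.5
  A2 <- cO * 1.2 + cH * 4.4
  so2 <- so2DualWavelength(matrix(A1), matrix(A2), tab, 573, 680)
  expect_equal(so2@values[1, 1], 1)
  cO <- 0.7; cH <- 0.7
  so2 <- so2DualWavelength(matrix(cO * 9.5 + cH * 9.5),
                           matrix(cO * 1.2 + cH * 4.4), tab, 573, 680)
  expect_equal(so2@values[1, 1], 0.5)
})

test_that("an isosbestic second wavelength is rejected", {
  tab <- .synthTable()
  expect_error(so2DualWavelength(matrix(1), matrix(1), tab, 680, 573),
               "isosbestic")
})

test_that("zero-total-absorbance pixels are flagged undefined", {
  tab <- .synthTable()
  so2 <- so2DualWavelength(matrix(c(0, 9.5)), matrix(c(0, 1.2)), tab,
                           573, 680)
  expect_true(so2@undefined[1, 1])
  expect_true(is.na(so2@values[1, 1]))
  expect_false(so2@undefined[2, 1])
})

test_that("ratioImage handles identity and zero denominators", {
  d <- array(0, c(2, 3, 3))
  d[1, , ] <- 2 * matrix(1:9, 3, 3)
  d[2, , ] <- matrix(1:9, 3, 3)
  d[2, 1, 1] <- 0
  cube <- HyperCube(d, c(550, 600), 12L)
  r <- ratioImage(cube, 1L, 2L)
  expect_true(is.na(r[1, 1]))
  expect_equal(as.numeric(r[-1]), rep(2, 8))
  expect_warning(ratioImage(cube, 2L, 2L), "identical")
})

test_that("cubeToMatrix flattens pixels column-major per band", {
  d <- array(seq_len(2 * 3 * 4), c(2, 3, 4))
  cube <- HyperCube(d, c(550, 600), 12L)
  m <- cubeToMatrix(cube)
  expect_equal(dim(m), c(2L, 12L))
  expect_equal(m[1, ], as.numeric(d[1, , ]))
  expect_equal(m[2, 5], d[2, 2, 2])
})

test_that("a truth-initialized factorization is an exact fixed point", {
  set.seed(15)
  L <- 12L
  P <- cbind(exp(-((1:L) - 3)^2 / 6), exp(-((1:L) - 9)^2 / 8)) + 0.05
  P <- sweep(P, 2L, colSums(P), "/")
  a <- c(0, 1, runif(100))
  Y <- P %*% rbind(a, 1 - a)
  um <- extractEndmembers(Y, 2L, rho = 0, init = P)
  expect_true(um@converged)
  expect_lt(max(abs(um@endmembers - P)), 1e-9)
})

test_that("a single end-member reduces to the Eq-11 centered column mean", {
  set.seed(16)
  Y <- matrix(runif(8 * 30, 1, 5), 8, 30)
  Y <- sweep(Y, 2L, colSums(Y), "/")
  um <- extractEndmembers(Y, 1L)
  # direct evaluation: A is a row of ones, so
  # P = (I - 11'/L) Y 1 / npix + 1/L
  L <- 8L
  direct <- as.numeric((diag(L) - matrix(1 / L, L, L)) %*%
                         rowMeans(Y) + 1 / L)
  expect_equal(as.numeric(um@endmembers), direct, tolerance = 1e-12)
})

test_that("abundances live on the simplex and maps reshape correctly", {
  set.seed(17)
  L <- 10L
  P <- cbind(seq(1, 2, length.out = L), seq(2, 1, length.out = L))
  P <- sweep(P, 2L, colSums(P), "/")
  a <- runif(24)
  Y <- P %*% rbind(a, 1 - a)
  um <- extractEndmembers(Y, 2L)
  expect_equal(colSums(um@abundances), rep(1, 24), tolerance = 1e-9)
  expect_true(all(um@abundances >= -1e-12))
  maps <- abundanceMaps(um, c(4L, 6L))
  expect_length(maps, 2L)
  expect_equal(dim(maps[[1L]]), c(4L, 6L))
  expect_equal(maps[[1L]][2, 3], um@abundances[1, 4 * 2 + 2])
  expect_error(abundanceMaps(um, c(5L, 5L)), "mismatch")
})

test_that("regularization shrinks end-members toward their mean", {
  set.seed(18)
  L <- 10L
  P <- cbind(seq(1, 3, length.out = L), seq(3, 1, length.out = L))
  P <- sweep(P, 2L, colSums(P), "/")
  a <- c(0, 1, runif(60))
  Y <- P %*% rbind(a, 1 - a)
  spreadOf <- function(rho) {
    um <- suppressWarnings(extractEndmembers(Y, 2L, rho = rho))
    sum((um@endmembers[, 1L] - um@endmembers[, 2L])^2)
  }
  expect_lt(spreadOf(5), spreadOf(0))
})
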