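test_that("compose and invert round trip points to machine precision", {
  set.seed(3)
  for (i in 1:20) {
    T1 <- RigidTransform(runif(1, -pi, pi), rnorm(2, 0, 10))
    T2 <- RigidTransform(runif(1, -pi, pi), rnorm(2, 0, 10))
    p <- matrix(rnorm(20, 0, 50), 10, 2)
    q <- applyTransform(composeTransforms(T2, T1), p)
    q2 <- applyTransform(T2, applyTransform(T1, p))
    expect_equal(q, q2, tolerance = 1e-12)
    back <- applyTransform(invertTransform(T1), applyTransform(T1, p))
    expect_equal(back, p, tolerance = 1e-12)
  }
})

test_that("transformAngle recovers the constructor angle", {
  for (a in c(-2, -0.5, 0, 0.3, 1.7))
    expect_equal(transformAngle(RigidTransform(a)), a, tolerance = 1e-12)
})

test_that("a reflection matrix is rejected by the class validity", {
  refl <- matrix(c(1, 0, 0, -1), 2, 2)
  expect_error(RigidTransform(rotation = refl), "determinant|rotation")
})

test_that("estimateRigid recovers identity from identical point sets", {
  p <- matrix(c(0, 0, 10, 0, 0, 10, 7, 3), 4, 2, byrow = TRUE)
  tr <- estimateRigid(p, p)
  expect_equal(tr@rotation, diag(2), tolerance = 1e-12)
  expect_equal(tr@translation, c(0, 0), tolerance = 1e-12)
})

test_that("estimateRigid recovers an exact 30-degree rotation plus shift", {
  set.seed(8)
  a <- 30 * pi / 180
  p <- matrix(rnorm(24, 0, 20), 12, 2)
  centroid <- colMeans(p)
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  q <- t(R %*% (t(p) - centroid) + centroid) +
    matrix(c(5, -3), 12, 2, byrow = TRUE)
  tr <- estimateRigid(p, q)
  expect_equal(transformAngle(tr), a, tolerance = 1e-9)
  expect_equal(max(abs(applyTransform(tr, p) - q)), 0, tolerance = 1e-9)
})

test_that("estimateRigid translation error stays below 0.2 px on average", {
  set.seed(12)
  errs <- replicate(100, {
    tr0 <- RigidTransform(runif(1, -0.1, 0.1), runif(2, -5, 5))
    p <- matrix(rnorm(100, 0, 30), 50, 2)
    q <- applyTransform(tr0, p) + matrix(rnorm(100, 0, 0.5), 50, 2)
    tr <- estimateRigid(p, q)
    sqrt(sum((tr@translation - tr0@translation)^2))
  })
  expect_lt(mean(errs), 0.2)
})

test_that("estimateRigid rejects degenerate input", {
  expect_error(estimateRigid(matrix(1, 1, 2), matrix(1, 1, 2)), "2 point")
  p <- matrix(5, 4, 2)
  expect_error(estimateRigid(p, p), "coincident")
})

test_that("estimateRigid agrees with a brute-force grid search", {
  set.seed(77)
  p <- matrix(rnorm(10, 0, 10), 5, 2)
  tr0 <- RigidTransform(0.21, c(1.4, -2.2))
  q <- applyTransform(tr0, p) + matrix(rnorm(10, 0, 0.2), 5, 2)
  # oracle: exhaustive search over angle x translation grid
  angles <- seq(0.1, 0.3, by = 0.002)
  best <- Inf
  bestA <- NA
  for (a in angles) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    tshift <- colMeans(q) - as.numeric(R %*% colMeans(p))
    r <- q - (t(R %*% t(p)) + matrix(tshift, 5, 2, byrow = TRUE))
    s <- sum(r^2)
    if (s < best) {
      best <- s
      bestA <- a
    }
  }
  tr <- estimateRigid(p, q)
  expect_lt(abs(transformAngle(tr) - bestA), 0.002)
})

test_that("warpImage with identity returns the image unchanged", {
  img <- matrix(runif(100), 10, 10)
  expect_equal(warpImage(img, RigidTransform(), "nearest"), img)
  expect_equal(warpImage(img, RigidTransform(), "bilinear"), img,
               tolerance = 1e-12)
})

test_that("warpImage shifts content by integer translations exactly", {
  img <- matrix(0, 12, 12)
  img[6, 4] <- 1
  # transform maps source to output: pixel (5, 3) 0-based moves by (+2, +3)
  out <- warpImage(img, RigidTransform(translation = c(2, 3)), "nearest")
  expect_equal(out[8, 7], 1)
  expect_equal(sum(out), 1)
})

test_that("out-of-frame samples take the declared fill value", {
  img <- matrix(5, 6, 6)
  out <- warpImage(img, RigidTransform(translation = c(4, 0)), "nearest",
                   fill = -1)
  expect_true(all(out[1:4, ] == -1))
  expect_true(all(out[5:6, ] == 5))
})
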