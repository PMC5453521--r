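test_that("otsuThreshold matches the exhaustive-search oracle", {
  set.seed(7)
  for (i in 1:25) {
    x <- c(rnorm(200, 40, 6), rnorm(150, 120, 15))
    if (i %% 2 == 0) x <- round(x)
    expect_identical(otsuThreshold(x)$threshold, bruteForceOtsu(x))
  }
})

test_that("otsuThreshold separates a clean bimodal image", {
  set.seed(1)
  img <- matrix(c(rpois(500, 30), rpois(500, 200)), 100, 10)
  ot <- otsuThreshold(img)
  expect_gt(ot$threshold, 30)
  expect_lt(ot$threshold, 200)
  expect_false(ot$degenerate)
  expect_equal(ot$omega0 + ot$omega1, 1)
  expect_lt(ot$mu0, ot$mu1)
})

test_that("a constant image is flagged degenerate", {
  ot <- otsuThreshold(matrix(7, 5, 5))
  expect_true(ot$degenerate)
  expect_equal(ot$threshold, 7)
  expect_equal(ot$sigma_b2, 0)
})

test_that("segmentation is invariant under positive affine rescaling", {
  set.seed(42)
  band <- matrix(rnorm(120 * 120, 1000, 50), 120, 120)
  band[40:60, 20:100] <- band[40:60, 20:100] - 600
  m1 <- localThresholdSegment(band, window = 50L)
  m2 <- localThresholdSegment(3.7 * band + 123, window = 50L)
  expect_identical(m1, m2)
})

test_that("dark structures become foreground, uniform noise does not", {
  set.seed(5)
  band <- matrix(rnorm(100 * 100, 2000, 30), 100, 100)
  band[45:55, ] <- band[45:55, ] - 1200
  m <- localThresholdSegment(band, window = 50L)
  expect_gt(mean(m[45:55, ]), 0.95)
  expect_lt(mean(m[c(1:35, 65:100), ]), 0.05)
})

test_that("a window larger than the image is rejected", {
  expect_error(localThresholdSegment(matrix(1:100, 10, 10), window = 50L),
               "window")
})

test_that("levelsetFilter drops small clutter and keeps the main region", {
  m <- matrix(FALSE, 80, 80)
  m[20:60, 35:45] <- TRUE        # 41 x 11 = 451 px main region
  m[5:8, 5:8] <- TRUE            # 16 px clutter
  m[70:74, 60:66] <- TRUE        # 35 px clutter
  out <- levelsetFilter(m, levelSetParams(min_component_area = 120L))
  expect_false(any(out[1:10, 1:10]))
  expect_false(any(out[68:76, 58:68]))
  expect_gt(sum(out & m), 0.8 * 451)
})

test_that("curvature flow never increases the component count", {
  set.seed(9)
  m <- matrix(runif(60 * 60) < 0.4, 60, 60)
  m[10:50, 25:35] <- TRUE
  out <- levelsetFilter(m, levelSetParams(min_component_area = 30L))
  nIn <- max(EBImage::bwlabel(1 * hsvreg:::.removeSmall(m, 30L)))
  nOut <- if (any(out)) max(EBImage::bwlabel(1 * out)) else 0L
  expect_lte(nOut, nIn)
})

test_that("an empty mask passes through the level-set filter", {
  out <- levelsetFilter(matrix(FALSE, 10, 10))
  expect_false(any(out))
  expect_identical(attr(out, "iterations"), 0L)
})

test_that("the filtered boundary is smoother than the thresholded one", {
  set.seed(31)
  m <- matrix(FALSE, 90, 90)
  m[30:60, 10:80] <- TRUE
  ragged <- m & matrix(runif(90 * 90) > 0.15, 90, 90)
  perim <- function(x) {
    sum(x & !rbind(FALSE, x[-nrow(x), ])) + sum(x & !rbind(x[-1, ], FALSE)) +
      sum(x & !cbind(FALSE, x[, -ncol(x)])) + sum(x & !cbind(x[, -1], FALSE))
  }
  out <- levelsetFilter(ragged, levelSetParams(min_component_area = 10L))
  expect_lt(perim(out), perim(ragged))
})

test_that("segmentCube segments every band and logs per-band diagnostics", {
  ph <- defaultPhantom()
  masks <- defaultMasks()
  expect_s4_class(masks, "MaskStack")
  expect_equal(nBands(masks), nBands(ph$cube))
  log <- file.path(tempdir(), "seg_log.tsv")
  sub <- HyperCube(ph$cube@data[1:3, , , drop = FALSE],
                   ph$cube@wavelengths[1:3], ph$cube@bitDepth)
  segmentCube(sub, logfile = log)
  tab <- read.delim(log)
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("band", "threshold", "sigma_b2", "iterations",
                    "degenerate") %in% names(tab)))
  expect_false(any(tab$degenerate))
})

test_that("per-band Dice against the phantom truth is at least 0.9", {
  ph <- defaultPhantom()
  masks <- defaultMasks()
  for (b in seq_len(nBands(ph$cube))) {
    truth <- warpImage(1 * ph$truth@vesselMask,
                       invertTransform(ph$truth@trueTransforms[[b]]),
                       interpolation = "nearest", fill = 0) > 0.5
    m <- getBand(masks, b)
    dice <- 2 * sum(m & truth) / (sum(m) + sum(truth))
    expect_gte(dice, 0.9)
  }
})
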