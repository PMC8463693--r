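## synthetic stripe pattern with a given orientation (degrees, y up)
stripeImage <- function(angleDeg, n = 256, period = 12) {
  a <- angleDeg * pi / 180
  ## phase varies along the normal to the stripes
  x <- matrix(rep(seq_len(n), each = n), n, n)      # column index
  y <- matrix(rep(n:1, n), n, n)                    # y counts up
  phase <- (-sin(a) * x + cos(a) * y) * 2 * pi / period
  sin(phase)^2
}

test_that("block tiling covers the image in row-major order", {
  g <- tileBlocks(c(512, 512))
  expect_equal(nBlocks(g), 4)
  expect_equal(blockOrigins(g),
               cbind(row = c(0L, 0L, 256L, 256L),
                     col = c(0L, 256L, 0L, 256L)))
  expect_equal(nBlocks(tileBlocks(c(300, 520))), 2)
  expect_equal(nBlocks(tileBlocks(matrix(0, 768, 512))), 6)
  expect_error(tileBlocks(c(255, 512)), "smaller than one")
  expect_equal(nBlocks(tileBlocks(c(64, 64), blockSize = 32)), 4)
})

test_that("ROI selection applies the coverage threshold per block", {
  ref <- matrix(0, 256, 1024)
  ref[, 1:13] <- 1          # ~5% of block 1
  ref[, 257:384] <- 1       # 50% of block 2
  ref[, 513:539] <- 1       # ~10.5% of block 3
  g <- tileBlocks(ref)
  expect_equal(selectRois(ref, g), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(selectRois(ref, g, signalThreshold = 0.01),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(selectRois(matrix(0, 256, 1024), g)))
  ## intensity floor: faint pixels stop counting as signal
  faint <- ref * 0.05
  expect_false(any(selectRois(faint, g, pixelThreshold = 0.1)))
  expect_error(selectRois(matrix(0, 128, 128), g), "dimensions")
})

test_that("block orientation recovers stripe patterns", {
  for (ang in c(0, 30, 75, 120)) {
    est <- blockOrientation(stripeImage(ang))$orientation
    expect_lt(axialDiff(est, ang), 3)
  }
  ## vertical stripes
  est <- blockOrientation(stripeImage(90))$orientation
  expect_lt(axialDiff(est, 90), 2)
})

test_that("block orientation is equivariant under image transposition", {
  ## transposing the image mirrors orientation about the 45-degree axis
  img <- stripeImage(30)
  a <- blockOrientation(img)$orientation
  b <- blockOrientation(t(img))$orientation
  expect_lt(axialDiff(a + b, 90) %% 180, 2)
})

test_that("a featureless block reports no orientation", {
  flat <- matrix(0.5, 64, 64)
  bo <- blockOrientation(flat)
  expect_true(is.na(bo$orientation))
  expect_equal(bo$nPixelsUsed, 0L)
})

test_that("sinMap folds the axial ambiguity onto [0, 1]", {
  expect_equal(sinMap(c(0, 180)), c(0, 0), tolerance = 1e-12)
  expect_equal(sinMap(90), 1)
  expect_equal(sinMap(45), sin(pi / 4), tolerance = 1e-12)
  expect_equal(sinMap(1), sinMap(179), tolerance = 1e-12)
  expect_error(sinMap(-5), "0, 180")
  expect_error(sinMap(190), "0, 180")
  expect_error(sinMap(NA_real_), "0, 180")
})

test_that("alignment coefficient has the exact limiting values", {
  expect_equal(alignmentCoefficient(rep(37, 100)), 1)
  expect_equal(alignmentCoefficient(c(0, 90)), 0, tolerance = 1e-12)
  expect_equal(alignmentCoefficient(c(45, 135)), 0, tolerance = 1e-12)
  ## invariance under rotation and the 180-degree axial identification
  set.seed(8)
  th <- runif(30, 0, 180)
  r0 <- alignmentCoefficient(th)
  expect_equal(alignmentCoefficient((th + 63) %% 180), r0,
               tolerance = 1e-12)
  expect_equal(alignmentCoefficient(th + 180), r0, tolerance = 1e-12)
  ## weighting: zero-weight members drop out
  expect_equal(alignmentCoefficient(c(10, 10, 100), c(1, 1, 0)), 1)
  expect_error(alignmentCoefficient(numeric()), "at least one")
  expect_error(alignmentCoefficient(c(1, 2), weights = c(1, -1)),
               "non-negative")
  expect_error(alignmentCoefficient(c(1, 2), weights = 1), "length")
})

test_that("alignment of a large uniform sample is near zero", {
  set.seed(123)
  expect_lt(alignmentCoefficient(runif(10000, 0, 180)), 0.05)
})

test_that("blockMetrics quantifies a striped quadrant image", {
  img <- matrix(0, 512, 512)
  img[1:256, 1:256] <- stripeImage(20)          # top-left block
  img[257:512, 257:512] <- stripeImage(110)     # bottom-right block
  bm <- blockMetrics(img)
  expect_equal(bm$block_id, c(1L, 4L))
  expect_lt(axialDiff(bm$orientation_deg[1], 20), 3)
  expect_lt(axialDiff(bm$orientation_deg[2], 110), 3)
  expect_equal(bm$sin_orientation, sinMap(bm$orientation_deg))
  expect_true(all(bm$alignment > 0.9))          # coherent stripes
  expect_true(all(bm$coverage > 0.4))
  ## an all-zero image yields an empty, correctly typed frame
  empty <- blockMetrics(matrix(0, 256, 256))
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("block_id", "row", "col", "coverage",
                        "orientation_deg", "sin_orientation",
                        "alignment", "n_pixels_used"))
})

test_that("blockMetrics excludes blocks via an external reference", {
  img <- matrix(0, 256, 512)
  img[, 1:256] <- stripeImage(45)
  img[, 257:512] <- stripeImage(135)
  ref <- matrix(0, 256, 512)
  ref[, 257:512] <- 1                            # only block 2 has reference
  bm <- blockMetrics(img, reference = ref)
  expect_equal(bm$block_id, 2L)
  expect_lt(axialDiff(bm$orientation_deg, 135), 2)
})

test_that("orientation recovery works on a rendered phantom", {
  spec <- PhantomSpec(256, 256, nFibers = 40, kappa = Inf,
                      meanOrientation = 55, thicknessRange = c(1, 1.8),
                      lengthRange = c(60, 120), seed = 17)
  ph <- generatePhantom(spec)
  imgs <- renderPPMPair(ph)
  mono <- toMonochrome(differentialImage(imgs$i0, imgs$i90))
  bm <- blockMetrics(mono, reference = imgs$shg)
  expect_equal(nrow(bm), 1)
  expect_lt(axialDiff(bm$orientation_deg, 55), 5)
  expect_gt(bm$alignment, 0.8)
})
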