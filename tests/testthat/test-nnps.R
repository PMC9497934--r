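# NNPS estimator: ROI tiling, detrending, the white-noise closed form, the
# Parseval identity, gain invariance and agreement with the windowed
# expectation oracle for a blurred chain.

test_that("half-overlapping tiling yields the documented ROI counts", {
  f1 <- gaussFrames(1, 1024L, 100, 1, 0.1, seed = 1)
  expect_length(extractROIs(f1, roiSide = 256L), 49L)
  expect_length(extractROIs(f1, roiSide = 128L), 225L)
  f2 <- gaussFrames(2, 1024L, 100, 1, 0.1, seed = 2)
  expect_length(extractROIs(f2, roiSide = 256L), 98L)
  # a smaller frame falls back to the largest centred multiple, with warning
  f3 <- gaussFrames(1, 300L, 100, 1, 0.1, seed = 3)
  expect_warning(rois <- extractROIs(f3, roiSide = 128L), "largest centred")
  expect_length(rois, 9L)
})

test_that("frames too small for a single ROI raise an insufficient-data error", {
  f <- gaussFrames(2, 100L, 50, 1, 0.1, seed = 4)
  expect_error(suppressWarnings(nnps2D(f, roiSide = 128L)),
               "insufficient-data")
  expect_error(nnps2D(f[1], roiSide = 64L), "at least 2")
})

test_that("detrending removes exactly the fitted surface", {
  n <- 64L
  x <- seq(-1, 1, length.out = n)
  X <- matrix(x, n, n, byrow = TRUE); Y <- matrix(x, n, n)
  expect_equal(max(abs(detrendROI(matrix(7, n, n), order = 0L))), 0,
               tolerance = 1e-10)
  plane <- 3 + 2 * X - 5 * Y
  expect_equal(max(abs(detrendROI(plane, order = 1L))), 0, tolerance = 1e-9)
  quad <- plane + 0.5 * X^2 - X * Y + 2 * Y^2
  expect_equal(max(abs(detrendROI(quad, order = 2L))), 0, tolerance = 1e-8)
  expect_gt(max(abs(detrendROI(quad, order = 1L))), 1e-3)
  # order-2 residual variance of white noise loses exactly p = 6 dof on average
  set.seed(11)
  rss <- replicate(200, sum(detrendROI(matrix(rnorm(n * n), n, n),
                                       order = 2L)^2))
  expect_equal(mean(rss), n * n - 6, tolerance = 0.01)
})

test_that("white-noise NNPS matches sigma^2 a^2 / mu^2 within 3 RSE per axial bin", {
  mu <- 1000; sig <- 12; a <- 0.1
  frames <- gaussFrames(4, 256L, mu, sig, a, seed = 21)
  spec <- suppressWarnings(nnps2D(frames, roiSide = 64L, detrendOrder = 0L))
  expect_identical(spec@nRois, 196L)
  expected <- sig^2 * a^2 / mu^2
  ax <- nnps1D(spec, "axial")
  # half-overlapping ROIs: count effectively independent ROIs as nRois / 4
  rse <- 1 / sqrt(14 * spec@nRois / 4)
  expect_true(all(abs(curveValues(ax) / expected - 1) < 3 * rse))
  expect_equal(mean(curveValues(ax)), expected, tolerance = 3 / sqrt(196))
})

test_that("the NNPS integral obeys the Parseval identity over the same ROIs", {
  frames <- gaussFrames(2, 256L, 500, 8, 0.14, seed = 31)
  a <- 0.14
  spec <- suppressWarnings(nnps2D(frames, roiSide = 64L, detrendOrder = 2L))
  rois <- suppressWarnings(extractROIs(frames, roiSide = 64L))
  rss <- vapply(rois, function(r) sum(detrendROI(r, order = 2L)^2),
                numeric(1))
  sbar <- mean(vapply(frames, function(f) mean(frameData(f)), numeric(1)))
  expect_equal(sum(spec@values), mean(rss) * a^2 / sbar^2,
               tolerance = 1e-10)
})

test_that("the NNPS is invariant under a global gain factor", {
  frames <- gaussFrames(2, 256L, 800, 10, 0.1, seed = 41)
  scaled <- lapply(frames, function(f)
    imageFrame(3.7 * frameData(f), pixelPitch(f)))
  s1 <- suppressWarnings(nnps2D(frames, roiSide = 64L))
  s2 <- suppressWarnings(nnps2D(scaled, roiSide = 64L))
  expect_equal(s1@values, s2@values, tolerance = 1e-12)
})

test_that("axial and radial reductions agree for an isotropic white field", {
  frames <- gaussFrames(6, 256L, 1000, 10, 0.1, seed = 51)
  spec <- suppressWarnings(nnps2D(frames, roiSide = 64L, detrendOrder = 0L))
  ax <- nnps1D(spec, "axial")
  ra <- nnps1D(spec, "radial")
  expect_equal(mean(curveValues(ax)), mean(curveValues(ra)),
               tolerance = 0.05)
  # both curves are flat: spread well below the level itself
  expect_lt(stats::sd(curveValues(ra)) / mean(curveValues(ra)), 0.1)
  expect_lte(max(frequencies(ax)), 1 / (2 * 0.1) + 1e-12)
})

test_that("the simulated blur-free chain reproduces its theoretical NNPS level", {
  cfg <- chainConfig(fluence = 2e4, pixelPitch = 0.1, electronicSigma = 4,
                     gain = 1.5, frameShape = c(256L, 256L), seed = 61)
  frames <- simulateFlatField(cfg, 6)
  spec <- suppressWarnings(nnps2D(frames, roiSide = 64L, detrendOrder = 0L))
  level <- mean(curveValues(nnps1D(spec, "axial")))
  expect_equal(level, theoreticalNNPS(cfg, 1), tolerance = 0.03)
  # electronic noise shows up as a flat additive offset above the quantum term
  cfg0 <- chainConfig(fluence = 2e4, pixelPitch = 0.1, gain = 1.5,
                      frameShape = c(256L, 256L), seed = 61)
  frames0 <- simulateFlatField(cfg0, 6)
  level0 <- mean(curveValues(nnps1D(suppressWarnings(
    nnps2D(frames0, roiSide = 64L, detrendOrder = 0L)), "axial")))
  expect_gt(level, level0)
  expect_equal(level0, 1 / 2e4, tolerance = 0.03)
})

test_that("averaging more ROIs shrinks the per-bin spread like 1/sqrt(n)", {
  spread <- function(nFrames, seed) {
    frames <- gaussFrames(nFrames, 256L, 1000, 10, 0.1, seed = seed)
    spec <- suppressWarnings(nnps2D(frames, roiSide = 64L,
                                    detrendOrder = 0L))
    v <- spec@values[-1]
    stats::sd(v) / mean(v)
  }
  r <- spread(8, 71) / spread(2, 72)
  expect_equal(r, 0.5, tolerance = 0.3)
})

test_that("a blurred chain matches the windowed periodogram expectation", {
  cfg <- chainConfig(fluence = 2e4, pixelPitch = 0.1, blurSigma = 0.08,
                     frameShape = c(256L, 256L), seed = 81)
  frames <- simulateFlatField(cfg, 8)
  spec <- suppressWarnings(nnps2D(frames, roiSide = 128L,
                                  detrendOrder = 0L))
  oracle <- expectedNNPS2D(cfg, 128L)
  emp <- axialCut(spec@values, spec@frequencyStep)
  th <- axialCut(oracle, spec@frequencyStep)
  ratio <- emp$v / th$v
  expect_equal(mean(ratio), 1, tolerance = 0.05)
  expect_true(all(abs(ratio - 1) < 0.25))
})
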