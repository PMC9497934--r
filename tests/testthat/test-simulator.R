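# Imaging-chain simulator: Poisson statistics, determinism, analytic edge
# rendering, phantom rendering and the closed-form MTF/NNPS it advertises.

test_that("flat-field pixels are Poisson with mean fluence x pitch^2", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1,
                     frameShape = c(512L, 512L), seed = 42)
  ff <- simulateFlatField(cfg, 4)
  px <- unlist(lapply(ff, function(f) as.vector(frameData(f))))
  expect_gte(length(px), 1e6)
  m <- mean(px)
  expected <- 1e4 * 0.1^2
  se <- sqrt(expected / length(px))
  expect_lt(abs(m - expected), 5 * se)
  # Fano factor of a Poisson process is 1
  expect_equal(var(px) / m, 1, tolerance = 0.01)
})

test_that("degenerate configurations give exact frames", {
  cfg0 <- chainConfig(fluence = 0, pixelPitch = 0.1,
                      frameShape = c(16L, 16L), seed = 1)
  expect_true(all(frameData(simulateFlatField(cfg0, 2)[[1]]) == 0))
  expect_error(chainConfig(fluence = 10, pixelPitch = 0.1,
                           frameShape = c(0L, 8L)), "config error")
})

test_that("identical config and seed give bit-identical frames", {
  cfg <- chainConfig(fluence = 5e3, pixelPitch = 0.14, blurSigma = 0.1,
                     electronicSigma = 2, frameShape = c(64L, 64L), seed = 77)
  a <- simulateFlatField(cfg, 3)
  b <- simulateFlatField(cfg, 3)
  for (i in 1:3)
    expect_identical(frameData(a[[i]]), frameData(b[[i]]))
  # sub-seeding by counter: frame i does not depend on how many are drawn
  c1 <- simulateFlatField(cfg, 1)
  expect_identical(frameData(a[[1]]), frameData(c1[[1]]))
  e1 <- simulateEdgeImage(cfg, 2.5)
  e2 <- simulateEdgeImage(cfg, 2.5)
  expect_identical(frameData(e1), frameData(e2))
})

test_that("simulator calls do not perturb the caller's random stream", {
  set.seed(123); ref <- rnorm(5)
  set.seed(123)
  invisible(simulateFlatField(chainConfig(fluence = 100, pixelPitch = 0.1,
                                          frameShape = c(8L, 8L), seed = 5), 1))
  expect_identical(rnorm(5), ref)
})

test_that("edge image matches the two flat levels away from the edge", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1,
                     frameShape = c(128L, 128L), seed = 3)
  e <- simulateEdgeImage(cfg, 2.5, edgeContrast = 0.8, noise = FALSE)
  d <- frameData(e)
  th <- 2.5 * pi / 180
  dist <- panelIQ:::edgeDistances(128L, 128L, 0.1, 2.5) / 0.1  # pixels
  far <- abs(dist) > 2
  hi <- 1e4 * 0.01
  expect_true(all(abs(d[far & dist > 0] - hi) < 1e-9 * hi))
  expect_true(all(abs(d[far & dist < 0] - 0.2 * hi) < 1e-9 * hi))
})

test_that("noiseless edge equals the aperture-integrated blurred step", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1, blurSigma = 0.1,
                     frameShape = c(96L, 96L), seed = 3)
  e <- simulateEdgeImage(cfg, 2.5, noise = FALSE)
  d <- panelIQ:::edgeDistances(96L, 96L, 0.1, 2.5)
  step <- 1e4 * 0.01
  oracle <- step * esfOracle(as.vector(d), 2.5, 1, 0.1, 0.1)
  expect_lt(max(abs(as.vector(frameData(e)) - oracle)), 1e-3 * step)
})

test_that("the rendered edge angle is recovered by the MTF module", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1, blurSigma = 0.05,
                     frameShape = c(256L, 256L), seed = 8)
  for (ang in c(1.8, 2.5)) {
    e <- simulateEdgeImage(cfg, ang, noise = FALSE)
    expect_lt(abs(estimateEdgeAngle(e) - ang), 0.05)
  }
  expect_error(simulateEdgeImage(cfg, 50), "domain error")
  expect_error(simulateEdgeImage(cfg, 0), "domain error")
})

test_that("phantom rendering respects contrast and layout checks", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1,
                     frameShape = c(128L, 128L), seed = 10)
  roiA <- roiRect(54, 54, 20, 20)
  roiB <- roiRect(8, 8, 20, 20)
  lay <- phantomLayout(data.frame(cx = 64, cy = 64, radius = 24,
                                  contrast = 0.2),
                       list(list(target = roiA, background = roiB)))
  ph <- simulatePhantom(cfg, lay, noise = FALSE)
  inner <- roiStats(ph, roiA)$mean
  outer <- roiStats(ph, roiB)$mean
  expect_equal(inner / outer, 0.8, tolerance = 1e-9)
  expect_equal(computeCOV(ph, roiB), 0)
  # overlapping ROI pair is rejected at construction
  expect_error(phantomLayout(data.frame(cx = 64, cy = 64, radius = 24,
                                        contrast = 0.2),
                             list(list(target = roiA,
                                       background = roiRect(60, 60, 20, 20)))),
               "overlap")
  # discs outside the frame are a layout error
  expect_error(simulatePhantom(cfg,
    phantomLayout(data.frame(cx = 5, cy = 5, radius = 24, contrast = 0.2))),
    "layout error")
})

test_that("zero-contrast phantom is statistically a flat field", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1,
                     frameShape = c(128L, 128L), seed = 20)
  lay <- phantomLayout(data.frame(cx = 64, cy = 64, radius = 24,
                                  contrast = 1e-12))
  ph <- simulatePhantom(cfg, lay)
  fl <- simulateFlatField(chainConfig(fluence = 1e4, pixelPitch = 0.1,
                                      frameShape = c(128L, 128L), seed = 21),
                          1)[[1]]
  tt <- t.test(as.vector(frameData(ph)), as.vector(frameData(fl)))
  expect_gt(tt$p.value, 0.01)
})

test_that("theoretical MTF matches its closed forms", {
  cfg <- chainConfig(fluence = 1, pixelPitch = 0.1, blurSigma = 0,
                     frameShape = c(8L, 8L), seed = 1)
  expect_identical(theoreticalMTF(cfg, 0), 1)
  expect_equal(theoreticalMTF(cfg, 5), 2 / pi, tolerance = 1e-12)
  # vanishing-aperture limit: pure Gaussian factor exp(-2 pi^2 sigma^2 f^2)
  cfgS <- chainConfig(fluence = 1, pixelPitch = 1e-6, blurSigma = 0.1,
                      frameShape = c(8L, 8L), seed = 1)
  expect_equal(theoreticalMTF(cfgS, 1), exp(-2 * pi^2 * 0.01),
               tolerance = 1e-6)
  expect_equal(exp(-2 * pi^2 * 0.01), 0.8209, tolerance = 1e-4)
  expect_error(theoreticalMTF(cfg, -1), "domain error")
})

test_that("theoretical NNPS has the white-noise value and expected monotonicities", {
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1, blurSigma = 0,
                     frameShape = c(8L, 8L), seed = 1)
  # blur-free, electronics-free chain: flat NNPS = 1/fluence
  f <- seq(0, 5, by = 0.5)
  expect_equal(theoreticalNNPS(cfg, f), rep(1e-4, length(f)),
               tolerance = 1e-12)
  # gain cancels when electronic noise is zero
  cfg2 <- chainConfig(fluence = 1e4, pixelPitch = 0.1, gain = 2,
                      frameShape = c(8L, 8L), seed = 1)
  expect_equal(theoreticalNNPS(cfg2, f), theoreticalNNPS(cfg, f))
  # electronic noise raises the NNPS at every frequency
  cfg3 <- chainConfig(fluence = 1e4, pixelPitch = 0.1, electronicSigma = 5,
                      frameShape = c(8L, 8L), seed = 1)
  expect_true(all(theoreticalNNPS(cfg3, f) > theoreticalNNPS(cfg, f)))
  expect_error(theoreticalNNPS(chainConfig(fluence = 0, pixelPitch = 0.1,
                                           frameShape = c(8L, 8L)), 1),
               "undefined-normalization")
})

test_that("thicker-scintillator blur lowers MTF and high-frequency quantum NNPS", {
  mk <- function(s) chainConfig(fluence = 2e4, pixelPitch = 0.1,
                                blurSigma = s, frameShape = c(8L, 8L))
  f <- seq(0.25, 5, by = 0.25)
  sig <- c(0.05, 0.1, 0.15)
  for (i in 1:2) {
    expect_true(all(theoreticalMTF(mk(sig[i + 1]), f) <
                      theoreticalMTF(mk(sig[i]), f)))
    hi <- f[f >= 2.5]
    expect_true(all(theoreticalNNPS(mk(sig[i + 1]), hi) <
                      theoreticalNNPS(mk(sig[i]), hi)))
  }
})
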