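# Restoration: degradation model contracts, PSF synthesis from an MTF,
# Wiener deconvolution round trips and the denoise-then-deconvolve workflow.

delta <- function(n) {
  k <- matrix(0, n, n); k[(n + 1) %/% 2, (n + 1) %/% 2] <- 1; k
}

gaussKernel <- function(sigmaPx, n) {
  x <- seq_len(n) - (n + 1) / 2
  g <- exp(-x^2 / (2 * sigmaPx^2))
  k <- outer(g, g)
  k / sum(k)
}

testScene <- function(L = 128L, seed = 2) {
  set.seed(seed)
  x <- matrix(100, L, L)
  x[32:96, 32:96] <- 140
  x[50:78, 50:78] <- 80
  imageFrame(x, 0.1)
}

test_that("a delta PSF with zero noise is the identity degradation", {
  img <- testScene()
  out <- degrade(img, degradationModel(delta(7)))
  expect_equal(frameData(out), frameData(img), tolerance = 1e-10)
})

test_that("degradation preserves the mean and enforces model contracts", {
  img <- testScene()
  k <- gaussKernel(1.5, 9)
  out <- degrade(img, degradationModel(k))
  expect_equal(mean(frameData(out)), mean(frameData(img)), tolerance = 1e-6)
  expect_error(degrade(img, new("DegradationModel", psf = delta(7),
                                noiseSigma = -1)), "noiseSigma")
  expect_error(degradationModel(2 * delta(7)), "sum to 1")
  big <- matrix(1 / 300^2, 300, 300)
  expect_error(degrade(img, degradationModel(big)), "model error")
  # seeded noise draws are reproducible and leave the caller's RNG alone
  m <- degradationModel(delta(5), noiseSigma = 3)
  a <- degrade(img, m, seed = 9); b <- degrade(img, m, seed = 9)
  expect_identical(frameData(a), frameData(b))
})

test_that("psfFromMTF reproduces a delta and a Gaussian kernel", {
  # flat MTF = 1 -> delta kernel
  f <- seq(0, 5, by = 0.05)
  flat <- new("MTFCurve", frequencies = f, values = rep(1, length(f)),
              nyquist = 5)
  k <- psfFromMTF(flat, pitch = 0.1, support = 9L)
  expect_equal(k, delta(9), tolerance = 1e-6)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  # Gaussian MTF (sigma = 0.12 mm at 0.1 mm pitch, negligible at Nyquist so
  # alias folding plays no role) -> sampled Gaussian kernel
  g <- gaussianMTFCurve(0.12, 0.1, step = 0.01)
  kg <- psfFromMTF(g, pitch = 0.1, support = 13L)
  ref <- gaussKernel(1.2, 13)
  expect_lt(max(abs(kg - ref)), 0.02 * max(ref))
  expect_error(psfFromMTF(g, pitch = 0.1, support = 8L), "odd")
  short <- new("MTFCurve", frequencies = seq(0, 2, 0.1),
               values = exp(-seq(0, 2, 0.1)), nyquist = 2)
  expect_error(psfFromMTF(short, pitch = 0.1, support = 9L),
               "invalid-curve")
})

test_that("Wiener deconvolution nearly inverts a noiseless Gaussian blur", {
  img <- testScene()
  curve <- gaussianMTFCurve(0.08, 0.1, step = 0.01)
  blurred <- degrade(img, degradationModel(psfFromMTF(curve, 0.1, 15L)))
  restored <- wienerDeconvolve(blurred, curve, nsr = 1e-6)
  rng <- diff(range(frameData(img)))
  expect_lt(interiorRMSE(restored, img) / rng, 0.01)
  expect_lt(interiorRMSE(restored, img), interiorRMSE(blurred, img))
  # the image mean is preserved by the pinned zero-frequency gain
  expect_equal(mean(frameData(restored)), mean(frameData(img)),
               tolerance = 1e-3)
  expect_error(wienerDeconvolve(blurred, curve, nsr = -1), "nsr")
})

test_that("degradation lowers MTF50 and restoration recovers it", {
  # base blur 0.05 mm puts the intrinsic MTF50 inside the Nyquist band
  cfg <- chainConfig(fluence = 1e4, pixelPitch = 0.1, blurSigma = 0.05,
                     frameShape = c(256L, 256L), seed = 6)
  edge <- simulateEdgeImage(cfg, 2.5, noise = FALSE)
  curve <- gaussianMTFCurve(0.1, 0.1, step = 0.01)
  blurred <- degrade(edge, degradationModel(psfFromMTF(curve, 0.1, 15L)))
  restored <- wienerDeconvolve(blurred, curve, nsr = 1e-4)
  f0 <- mtf50(measureMTF(edge))
  fb <- mtf50(measureMTF(blurred))
  fr <- mtf50(measureMTF(restored))
  expect_lt(fb, f0)
  expect_gt(fr, fb)
  expect_equal(fr, f0, tolerance = 0.1)
})

test_that("deconvolution amplifies high-frequency noise", {
  set.seed(14)
  L <- 128L
  noise <- matrix(rnorm(L * L, 0, 1), L)
  img <- imageFrame(100 + noise, 0.1)
  curve <- gaussianMTFCurve(0.08, 0.1, aperture = TRUE, step = 0.01)
  out <- wienerDeconvolve(img, curve, nsr = 1e-4)
  highVar <- function(m) {
    F2 <- Mod(stats::fft(m - mean(m)))^2
    R <- sqrt(outer(dftFreqsLocal(L)^2, dftFreqsLocal(L)^2, `+`))
    mean(F2[R > 0.6 * 0.5])
  }
  dftFreqsLocal <- function(n) {
    k <- 0:(n - 1); ifelse(k > n / 2, k - n, k) / n
  }
  expect_gt(highVar(frameData(out)), 2 * highVar(frameData(img)))
})

test_that("adaptive denoising reduces noise and is the identity at nv = 0", {
  img <- testScene()
  same <- denoiseAdaptive(img, noiseVar = 0)
  expect_equal(frameData(same), frameData(img), tolerance = 1e-10)
  noisy <- degrade(img, degradationModel(delta(5), noiseSigma = 5), seed = 3)
  den <- denoiseAdaptive(noisy, window = 5L, noiseVar = 25)
  flat <- roiRect(4, 4, 24, 24)           # inside the constant background
  expect_lt(roiStats(den, flat)$sd^2, 0.2 * roiStats(noisy, flat)$sd^2)
  expect_lt(interiorRMSE(den, img), interiorRMSE(noisy, img))
  expect_error(denoiseAdaptive(img, window = 4L), "odd")
  # "auto" estimates a usable noise floor without being told sigma
  auto <- denoiseAdaptive(noisy)
  expect_lt(interiorRMSE(auto, img), interiorRMSE(noisy, img))
})

test_that("denoising before deconvolution beats deconvolution alone", {
  img <- testScene()
  curve <- gaussianMTFCurve(0.08, 0.1, step = 0.01)
  model <- degradationModel(psfFromMTF(curve, 0.1, 15L), noiseSigma = 2)
  obs <- degrade(img, model, seed = 8)
  direct <- wienerDeconvolve(obs, curve, nsr = 1e-4)
  staged <- wienerDeconvolve(denoiseAdaptive(obs, noiseVar = 4), curve,
                             nsr = 1e-4)
  expect_lt(interiorRMSE(staged, img), interiorRMSE(direct, img))
})
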