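# Restoration of blurred, noisy radiographs: the degradation model
# observed = PSF ** clean + noise, an adaptive local minimum-mean-square
# denoiser, synthesis of a radially symmetric PSF from a measured 1-D MTF,
# and Wiener deconvolution. The intended workflow is denoise first, then
# deconvolve: deconvolution is high-pass and amplifies whatever noise is
# left.

#' Construct a degradation model
#'
#' @param psf non-negative 2-D kernel; must sum to 1 within 1e-6.
#' @param noiseSigma additive Gaussian noise sd, signal units.
#' @return A \linkS4class{DegradationModel}.
#' @export
degradationModel <- function(psf, noiseSigma = 0) {
  new("DegradationModel", psf = psf, noiseSigma = as.numeric(noiseSigma))
}

# reflect-pad a matrix by pr rows and pc columns on each side
padSymmetric <- function(m, pr, pc) {
  H <- nrow(m); W <- ncol(m)
  if (pr >= H || pc >= W)
    stop("padding exceeds image size")
  ri <- c(pr:1, 1:H, H:(H - pr + 1L))[seq_len(H + 2L * pr)]
  ci <- c(pc:1, 1:W, W:(W - pc + 1L))[seq_len(W + 2L * pc)]
  if (pr == 0L) ri <- 1:H
  if (pc == 0L) ci <- 1:W
  m[ri, ci, drop = FALSE]
}

# 2-D convolution with symmetric (reflective) boundary handling, via FFT
conv2Symmetric <- function(m, kern) {
  kr <- nrow(kern); kc <- ncol(kern)
  pr <- kr %/% 2L; pc <- kc %/% 2L
  pad <- padSymmetric(m, pr, pc)
  P1 <- nrow(pad); P2 <- ncol(pad)
  K <- matrix(0, P1, P2)
  cr <- pr + 1L; cc <- pc + 1L       # kernel centre
  ri <- ((seq_len(kr) - cr) %% P1) + 1L
  ci <- ((seq_len(kc) - cc) %% P2) + 1L
  K[ri, ci] <- kern
  out <- Re(stats::fft(stats::fft(pad) * stats::fft(K), inverse = TRUE)) /
    (P1 * P2)
  out[(pr + 1L):(pr + nrow(m)), (pc + 1L):(pc + ncol(m)), drop = FALSE]
}

#' Apply a degradation model to a frame
#'
#' Blurs the frame by 2-D convolution with the model PSF (symmetric boundary
#' handling) and adds Gaussian noise of the model's sd.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param model a \linkS4class{DegradationModel}; the PSF must be smaller
#'   than the image and normalized to unit sum.
#' @param seed optional seed for the noise draw.
#' @return The degraded \linkS4class{ImageFrame}.
#' @export
degrade <- function(image, model, seed = NULL) {
  stopifnot(is(image, "ImageFrame"), is(model, "DegradationModel"))
  if (abs(sum(model@psf) - 1) > 1e-6)
    stop("model error: PSF is not normalized to unit sum")
  if (nrow(model@psf) >= nrow(image@data) ||
      ncol(model@psf) >= ncol(image@data))
    stop("model error: PSF must be smaller than the image")
  out <- conv2Symmetric(image@data, model@psf)
  if (model@noiseSigma > 0) {
    noise <- if (is.null(seed))
      stats::rnorm(length(out), 0, model@noiseSigma)
    else withSeed(seed, stats::rnorm(length(out), 0, model@noiseSigma))
    out <- out + matrix(noise, nrow(out))
  }
  imageFrame(out, image@pixelPitch)
}

# local mean over a w x w window with symmetric padding, via running sums
boxMean <- function(m, w) {
  hw <- (w - 1L) %/% 2L
  run1 <- function(x) {             # along rows
    pad <- padSymmetric(x, hw, 0L)
    cs <- rbind(0, apply(pad, 2, cumsum))
    (cs[(1:nrow(x)) + w, , drop = FALSE] -
       cs[1:nrow(x), , drop = FALSE]) / w
  }
  t(run1(t(run1(m))))
}

#' Adaptive local minimum-mean-square denoising
#'
#' Per-pixel Wiener-type estimate from local statistics in a square window:
#' output = m + max(0, v - nv) / max(v, nv) * (input - m), with m and v the
#' local mean and variance and nv the noise variance. With \code{noiseVar =
#' "auto"} the noise variance is the median of the local variances. A zero
#' noise variance reduces the filter to the identity.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param window odd window size >= 3 (default 5).
#' @param noiseVar noise variance in squared signal units, or \code{"auto"}.
#' @return The denoised \linkS4class{ImageFrame}.
#' @export
denoiseAdaptive <- function(image, window = 5L, noiseVar = "auto") {
  stopifnot(is(image, "ImageFrame"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3")
  x <- image@data
  m <- boxMean(x, window)
  v <- pmax(boxMean(x^2, window) - m^2, 0)
  nv <- if (identical(noiseVar, "auto")) stats::median(v)
        else as.numeric(noiseVar)
  den <- pmax(v, nv)
  gainMap <- ifelse(den > 0, pmax(v - nv, 0) / den, 0)
  imageFrame(m + gainMap * (x - m), image@pixelPitch)
}

# evaluate a 1-D frequency curve at radial frequencies, extending beyond its
# last sample log-linearly (never upward) and clipping small negatives at 0
radialTransfer <- function(curve, r) {
  f <- curve@frequencies; v <- curve@values
  if (any(v < -1e-3))
    stop("invalid-curve error: curve has values below -1e-3")
  v <- pmax(v, 0)
  fmax <- max(f)
  out <- stats::approx(f, v, xout = pmin(r, fmax), rule = 2)$y
  beyond <- r > fmax
  if (any(beyond)) {
    n <- length(v)
    if (v[n] > 0 && v[n - 1L] > 0) {
      slope <- min((log(v[n]) - log(v[n - 1L])) / (f[n] - f[n - 1L]), 0)
      out[beyond] <- v[n] * exp(slope * (r[beyond] - fmax))
    } else out[beyond] <- 0
  }
  out
}

# wrapped DFT frequency magnitudes (lp/mm) for an n-point axis at pitch a
dftFreqs <- function(n, a) {
  k <- 0:(n - 1)
  ifelse(k > n / 2, k - n, k) / (n * a)
}

#' Synthesize a 2-D PSF from a 1-D MTF
#'
#' Assembles a radially symmetric 2-D transfer magnitude from the 1-D curve
#' (log-linear extension beyond the last sample), inverse-transforms it,
#' truncates to the requested support, clips negative ringing at zero and
#' renormalizes to unit sum.
#'
#' @param curve an \linkS4class{MTFCurve} defined up to the Nyquist
#'   frequency.
#' @param pitch pixel pitch of the target image, mm.
#' @param support odd kernel side, pixels.
#' @return A support x support kernel with unit sum.
#' @export
psfFromMTF <- function(curve, pitch, support) {
  stopifnot(is(curve, "MTFCurve"))
  support <- as.integer(support)
  if (support %% 2L == 0L) stop("support must be odd")
  if (max(curve@frequencies) < 1 / (2 * pitch) - 1e-9)
    stop("invalid-curve error: curve must be defined up to Nyquist = ",
         signif(1 / (2 * pitch), 4), " lp/mm")
  M <- max(8L * support, 256L)
  fr <- dftFreqs(M, pitch)
  R <- sqrt(outer(fr^2, fr^2, `+`))
  H <- matrix(radialTransfer(curve, as.vector(R)), M)
  psf <- Re(stats::fft(H, inverse = TRUE)) / M^2
  # shift the kernel centre from (1,1) to the matrix centre, then crop
  ctr <- M %/% 2L + 1L
  psf <- psf[c(ctr:M, 1:(ctr - 1L)), c(ctr:M, 1:(ctr - 1L))]
  hw <- support %/% 2L
  psf <- psf[(ctr - hw):(ctr + hw), (ctr - hw):(ctr + hw)]
  psf <- pmax(psf, 0)
  psf / sum(psf)
}

#' Wiener deconvolution with an MTF-derived transfer function
#'
#' Frequency-domain filter H / (H^2 + nsr), with H the radially symmetric
#' transfer assembled from the 1-D curve and nsr the noise-to-signal power
#' ratio. The zero-frequency gain is pinned to 1, so the image mean is
#' preserved. Deconvolution is high-pass: high-frequency noise is amplified,
#' which is why denoising first is recommended.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param curve an \linkS4class{MTFCurve} describing the blur to invert.
#' @param nsr noise-to-signal power ratio, >= 0 (default 1e-2).
#' @param pad symmetric padding width, pixels (default 32; reduces
#'   wrap-around ringing).
#' @return The restored \linkS4class{ImageFrame}.
#' @export
wienerDeconvolve <- function(image, curve, nsr = 1e-2, pad = 32L) {
  stopifnot(is(image, "ImageFrame"), is(curve, "MTFCurve"))
  if (nsr < 0) stop("nsr must be >= 0")
  x <- image@data
  pr <- min(as.integer(pad), nrow(x) - 1L)
  pc <- min(as.integer(pad), ncol(x) - 1L)
  padded <- padSymmetric(x, pr, pc)
  P1 <- nrow(padded); P2 <- ncol(padded)
  R <- sqrt(outer(dftFreqs(P1, image@pixelPitch)^2,
                  dftFreqs(P2, image@pixelPitch)^2, `+`))
  H <- matrix(radialTransfer(curve, as.vector(R)), P1)
  if (nsr == 0 && any(H == 0))
    stop("ill-posed error: nsr = 0 with zero transfer bins")
  filt <- H / (H^2 + nsr)
  filt[1L, 1L] <- 1
  out <- Re(stats::fft(stats::fft(padded) * filt, inverse = TRUE)) / (P1 * P2)
  imageFrame(out[(pr + 1L):(pr + nrow(x)), (pc + 1L):(pc + ncol(x)),
                 drop = FALSE], image@pixelPitch)
}
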