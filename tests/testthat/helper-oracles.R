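# Independent oracles used across the suite. These deliberately avoid the
# package's estimator code paths: closed forms, fine quadrature and direct
# DFT expectations.

# 2-D NNPS of the simulated chain on the L x L DFT grid of an ROI:
# quantum shot noise shaped by the squared Gaussian blur and pixel aperture,
# folded over the pixel sampling grid, plus the flat electronic term.
theoreticalNNPS2Dgrid <- function(cfg, L) {
  a <- cfg@pixelPitch
  k <- 0:(L - 1)
  fr <- ifelse(k > L / 2, k - L, k) / (L * a)
  mu <- cfg@gain * cfg@fluence * a^2
  S <- matrix(0, L, L)
  sincf <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  for (ka in -2:2) for (la in -2:2) {
    U <- matrix(fr + ka / a, L, L)
    V <- matrix(fr + la / a, L, L, byrow = TRUE)
    S <- S + exp(-4 * pi^2 * cfg@blurSigma^2 * (U^2 + V^2)) *
      sincf(pi * a * U)^2 * sincf(pi * a * V)^2
  }
  S / cfg@fluence + (cfg@electronicSigma * a)^2 / mu^2
}

# Expected value of the rectangular-window (unmodified) ROI periodogram of a
# process with the chain's true spectrum: true spectrum -> pixel covariance
# -> Bartlett-weighted covariance -> expected periodogram. This accounts for
# the Fejer smoothing the finite ROI window applies to a steep spectrum.
expectedNNPS2D <- function(cfg, L) {
  a <- cfg@pixelPitch
  S <- theoreticalNNPS2Dgrid(cfg, L)
  C <- Re(stats::fft(S, inverse = TRUE)) / (L^2 * a^2)   # pixel covariance / mu^2
  m <- 0:(L - 1)
  m <- ifelse(m > L / 2, m - L, m)
  tri <- (L - abs(m))
  W <- outer(tri, tri) * C
  Re(stats::fft(W)) * a^2 / L^2
}

# axial reduction identical in definition to nnps1D but written directly
axialCut <- function(V, df) {
  L <- nrow(V)
  offs <- c(2:8, L - (0:6))
  half <- L %/% 2L
  vals <- vapply(0:half, function(kk) {
    i <- kk + 1L
    mean(c(V[i, offs], V[offs, i]))
  }, numeric(1))
  list(f = (0:half) * df, v = vals)
}

# transmission of the tilted blurred edge averaged over one pixel aperture,
# by fine midpoint quadrature (64 x 64) of the closed-form blurred step
esfOracle <- function(d, angle, contrast, sigma, pitch, nq = 64L) {
  th <- angle * pi / 180
  off <- ((seq_len(nq) - 0.5) / nq - 0.5) * pitch
  out <- numeric(length(d))
  for (du in off) for (dv in off) {
    t <- d + du * cos(th) - dv * sin(th)
    b <- if (sigma > 0) stats::pnorm(t / sigma) else (t > 0) + 0.5 * (t == 0)
    out <- out + (1 - contrast) + contrast * b
  }
  out / nq^2
}

# analytic Gaussian-blur MTF curve (with pitch aperture folded in only when
# aperture = TRUE), sampled densely to Nyquist
gaussianMTFCurve <- function(sigma, pitch, aperture = FALSE, step = 0.02) {
  nyq <- 1 / (2 * pitch)
  f <- seq(0, nyq, by = step)
  v <- exp(-2 * pi^2 * sigma^2 * f^2)
  if (aperture) {
    s <- ifelse(f == 0, 1, sin(pi * pitch * f) / (pi * pitch * f))
    v <- v * abs(s)
  }
  new("MTFCurve", frequencies = f, values = v, nyquist = nyq)
}

# i.i.d. Gaussian flat frames (independent of the simulator)
gaussFrames <- function(n, L, mu, sigma, pitch, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    imageFrame(matrix(stats::rnorm(L * L, mu, sigma), L, L), pitch))
}

# RMSE between two frames' interiors, excluding a margin of pixels
interiorRMSE <- function(a, b, margin = 16L) {
  A <- frameData(a); B <- frameData(b)
  r <- (margin + 1L):(nrow(A) - margin)
  c <- (margin + 1L):(ncol(A) - margin)
  sqrt(mean((A[r, c] - B[r, c])^2))
}

# value of a curve at a frequency, by linear interpolation
curveAt <- function(curve, f) {
  stats::approx(frequencies(curve), curveValues(curve), xout = f)$y
}
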