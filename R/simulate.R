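# Forward model of an indirect-conversion flat panel. Photons arrive as a
# Poisson process at the detected fluence, scintillator light spread is an
# isotropic Gaussian, the square pixel aperture integrates the light field,
# a linear gain maps detected photons to signal units and Gaussian electronic
# noise is added per pixel. The model's MTF and NNPS are known in closed form
# (theoreticalMTF / theoreticalNNPS), so the estimators can be validated
# without detector hardware.

#' Construct an imaging-chain configuration
#'
#' Either give the detected photon fluence directly, or give a beam quality
#' plus air kerma and let the registry convert (optionally scaled by a
#' quantum absorption fraction).
#'
#' @param fluence detected photon fluence, photons/mm^2 (omit when using
#'   \code{beam} + \code{kerma}).
#' @param pixelPitch pixel pitch, mm.
#' @param blurSigma Gaussian scintillator blur sigma, mm.
#' @param gain signal units per detected photon.
#' @param electronicSigma additive electronic noise sigma, signal units.
#' @param frameShape frame dimensions, c(rows, cols).
#' @param seed master seed; frames are reproducible bit-for-bit.
#' @param beam beam quality name or \linkS4class{BeamQuality} (with
#'   \code{kerma}, used when \code{fluence} is missing).
#' @param kerma air kerma, uGy.
#' @param absorbedFraction fraction of the incident fluence detected
#'   (scales the registry conversion; default 1).
#' @return A \linkS4class{ChainConfig}.
#' @examples
#' cfg <- chainConfig(pixelPitch = 0.1, beam = "RQA5", kerma = 2.5)
#' @export
chainConfig <- function(fluence = NULL, pixelPitch, blurSigma = 0, gain = 1,
                        electronicSigma = 0, frameShape = c(256L, 256L),
                        seed = 1L, beam = NULL, kerma = NULL,
                        absorbedFraction = 1) {
  if (is.null(fluence)) {
    if (is.null(beam) || is.null(kerma))
      stop("config error: give either 'fluence' or both 'beam' and 'kerma'")
    bq <- if (is(beam, "BeamQuality")) beam else beamQuality(beam)
    fluence <- absorbedFraction * fluenceFromKerma(bq, kerma)
  }
  if (any(frameShape < 1))
    stop("config error: frameShape dimensions must be positive")
  new("ChainConfig", fluence = as.numeric(fluence),
      pixelPitch = as.numeric(pixelPitch), blurSigma = as.numeric(blurSigma),
      gain = as.numeric(gain), electronicSigma = as.numeric(electronicSigma),
      frameShape = as.integer(frameShape), seed = as.integer(seed))
}

#' Illustrative simulator presets for the three registered detectors
#'
#' Returns a chain configuration that mimics one of the registered detectors.
#' The pixel pitch comes from the specification registry; the blur sigma,
#' absorbed fluence fraction, gain and electronic noise are ILLUSTRATIVE
#' values (the physical panels' values are not public), chosen so that the
#' scintillator-thickness trade-off has its expected qualitative signature:
#' the standard-thickness panel has the highest MTF while the thick,
#' fine-pitch panel has the lowest NNPS and the highest DQE.
#'
#' @param name detector name (see \code{\link{detectorSpec}}).
#' @param kerma air kerma, uGy (RQA5 beam).
#' @param frameShape frame dimensions, c(rows, cols).
#' @param seed master seed.
#' @return List with elements \code{config} (a \linkS4class{ChainConfig}),
#'   \code{beam}, \code{kerma}, \code{detector} and \code{absorbedFraction}.
#' @export
illustrativePreset <- function(name, kerma = 2.5,
                               frameShape = c(512L, 512L), seed = 1L) {
  spec <- detectorSpec(name)
  pars <- switch(normalizeKey(spec@name),
    "FXRD4343VAW" =     list(blur = 0.100, qde = 0.55, gain = 1.0, esig = 10),
    "FXRD4343VAWPLUS" = list(blur = 0.115, qde = 0.70, gain = 1.5, esig = 10),
    "FXRD4343FAW" =     list(blur = 0.120, qde = 0.75, gain = 1.6, esig = 3),
    stop("no illustrative preset for detector '", name, "'"))
  cfg <- chainConfig(pixelPitch = spec@pixelPitch / 1000,
                     blurSigma = pars$blur, gain = pars$gain,
                     electronicSigma = pars$esig, frameShape = frameShape,
                     seed = seed, beam = "RQA5", kerma = kerma,
                     absorbedFraction = pars$qde)
  list(config = cfg, beam = "RQA5", kerma = kerma, detector = spec@name,
       absorbedFraction = pars$qde)
}

# deterministic per-frame sub-seed from the master seed and a frame counter
subSeed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 1000003 * counter) %% 2147483647)
}

# Poisson sample with Gaussian approximation above mean 1000 (documented
# speed switch; the relative skewness there is < 0.032)
rpoisCount <- function(mu) {
  out <- numeric(length(mu))
  hi <- mu > 1000
  if (any(hi)) out[hi] <- stats::rnorm(sum(hi), mu[hi], sqrt(mu[hi]))
  if (any(!hi)) out[!hi] <- stats::rpois(sum(!hi), mu[!hi])
  out
}

# periodic Gaussian blur of a matrix sampled at spacing h (mm), sigma in mm
blurPeriodic <- function(mat, sigma, h) {
  if (sigma <= 0) return(mat)
  kern1d <- function(n) {
    x <- 0:(n - 1)
    x <- ifelse(x > n / 2, x - n, x) * h
    g <- exp(-x^2 / (2 * sigma^2))
    stats::fft(g / sum(g))
  }
  G <- outer(kern1d(nrow(mat)), kern1d(ncol(mat)))
  Re(stats::fft(stats::fft(mat) * G, inverse = TRUE)) / length(mat)
}

# sum s x s blocks of a matrix (exact pixel-aperture integration of a field
# that is piecewise constant on sub-pixel cells)
blockSum <- function(m, s) {
  H <- nrow(m) %/% s; W <- ncol(m) %/% s
  dim(m) <- c(s, H, s, W)
  a <- colSums(m)               # (H, s, W)
  a <- aperm(a, c(2L, 1L, 3L))  # (s, H, W)
  colSums(a)                    # (H, W)
}

# apply gain and electronic noise to a matrix of photon counts
readout <- function(counts, cfg, noise) {
  out <- cfg@gain * counts
  if (noise && cfg@electronicSigma > 0)
    out <- out + stats::rnorm(length(out), 0, cfg@electronicSigma)
  matrix(out, nrow = nrow(counts))
}

#' Simulate uniform-exposure ("white") frames
#'
#' Each pixel is the gain times a (Gaussian-blurred) Poisson photon count of
#' mean fluence x pitch^2, plus electronic noise. With blur, photons are
#' sampled on a sub-pixel grid, blurred, and aggregated, so that the
#' blur-induced noise correlation the NNPS measures is physically present.
#' Frames are independent given sub-seeds derived from the master seed by a
#' counter, so frame i is reproducible regardless of how many frames are
#' requested.
#'
#' @param cfg a \linkS4class{ChainConfig}.
#' @param nFrames number of frames (>= 1).
#' @param noise simulate quantum and electronic noise (set \code{FALSE} for
#'   the noiseless mean frame).
#' @param supersample sub-pixel grid factor used when \code{blurSigma > 0}.
#' @return List of \linkS4class{ImageFrame}s.
#' @export
simulateFlatField <- function(cfg, nFrames, noise = TRUE, supersample = 4L) {
  stopifnot(is(cfg, "ChainConfig"), nFrames >= 1)
  H <- cfg@frameShape[1L]; W <- cfg@frameShape[2L]
  a <- cfg@pixelPitch
  meanCount <- cfg@fluence * a^2
  lapply(seq_len(nFrames), function(i) {
    frame <- withSeed(subSeed(cfg@seed, i), {
      if (!noise) {
        counts <- matrix(meanCount, H, W)
      } else if (cfg@blurSigma > 0 && cfg@fluence > 0) {
        s <- as.integer(supersample)
        sub <- matrix(rpoisCount(rep(meanCount / s^2, (H * s) * (W * s))),
                      H * s, W * s)
        sub <- blurPeriodic(sub, cfg@blurSigma, a / s)
        counts <- blockSum(sub, s)
      } else {
        counts <- matrix(rpoisCount(rep(meanCount, H * W)), H, W)
      }
      readout(counts, cfg, noise)
    })
    imageFrame(frame, a)
  })
}

# signed perpendicular distance (mm) of pixel centres from an edge through
# the frame centre, tilted `angle` degrees from the column (vertical) axis
edgeDistances <- function(H, W, a, angle) {
  th <- angle * pi / 180
  xd <- (seq_len(W) - (W + 1) / 2) * a
  yd <- (seq_len(H) - (H + 1) / 2) * a
  outer(-yd * sin(th), xd * cos(th), `+`)
}

# blurred-step transmission at perpendicular distance t (mm): dark side
# transmits (1 - contrast) of the fluence
stepTransmission <- function(t, contrast, sigma) {
  b <- if (sigma > 0) stats::pnorm(t / sigma) else (t > 0) + 0.5 * (t == 0)
  (1 - contrast) + contrast * b
}

#' Simulate a tilted-edge image
#'
#' Renders a straight edge through the frame centre at the given tilt from
#' the pixel-column axis. The mean signal is exact: the Gaussian-blurred step
#' has a closed form (error function), and the pixel-aperture integral is
#' evaluated by supersampling each pixel at \code{supersample^2} points.
#' Quantum noise is then drawn per pixel from the aperture-integrated mean
#' (blur-induced noise correlation is reproduced only in flat-field frames,
#' where the NNPS is estimated).
#'
#' @param cfg a \linkS4class{ChainConfig}.
#' @param angle edge tilt from the column axis, degrees, in (0, 45).
#' @param edgeContrast fraction of the fluence blocked on the dark side;
#'   1 = opaque edge (the default, an opaque tungsten foil).
#' @param noise simulate quantum and electronic noise.
#' @param supersample sub-pixel points per axis for the aperture integral
#'   (>= 8 recommended; default 8).
#' @return An \linkS4class{ImageFrame}.
#' @export
simulateEdgeImage <- function(cfg, angle, edgeContrast = 1, noise = TRUE,
                              supersample = 8L) {
  stopifnot(is(cfg, "ChainConfig"))
  if (!is.finite(angle) || angle <= 0 || angle >= 45)
    stop("domain error: edge angle must lie in (0, 45) degrees")
  if (edgeContrast <= 0 || edgeContrast > 1)
    stop("domain error: edgeContrast must lie in (0, 1]")
  H <- cfg@frameShape[1L]; W <- cfg@frameShape[2L]
  a <- cfg@pixelPitch; s <- as.integer(supersample)
  th <- angle * pi / 180
  d <- edgeDistances(H, W, a, angle)
  Tbar <- matrix(0, H, W)
  off <- ((seq_len(s) - 0.5) / s - 0.5) * a
  for (du in off) for (dv in off)
    Tbar <- Tbar + stepTransmission(d + du * cos(th) - dv * sin(th),
                                    edgeContrast, cfg@blurSigma)
  Tbar <- Tbar / s^2
  meanCounts <- cfg@fluence * a^2 * Tbar
  frame <- withSeed(subSeed(cfg@seed, 1L), {
    counts <- if (noise) matrix(rpoisCount(meanCounts), H, W) else meanCounts
    readout(counts, cfg, noise)
  })
  imageFrame(frame, a)
}

#' Construct a contrast phantom layout
#'
#' @param discs data.frame with columns \code{cx, cy} (0-based pixel
#'   centres), \code{radius} (pixels), \code{contrast} (fraction in (0, 1]).
#' @param roiPairs list of \code{list(target=, background=)}
#'   \linkS4class{ROIRect} pairs.
#' @return A \linkS4class{PhantomLayout}.
#' @export
phantomLayout <- function(discs, roiPairs = list()) {
  new("PhantomLayout", discs = as.data.frame(discs), roiPairs = roiPairs)
}

#' Simulate a disc-on-background contrast phantom
#'
#' Discs modulate the incident fluence by their contrast fraction before
#' blur and noise, emulating the target/background ROI geometry used for
#' CNR and COV measurements.
#'
#' @param cfg a \linkS4class{ChainConfig}.
#' @param layout a \linkS4class{PhantomLayout}; discs must lie inside the
#'   frame and the ROIs of each pair must not overlap.
#' @param noise simulate quantum and electronic noise.
#' @param supersample sub-pixel rendering factor.
#' @return An \linkS4class{ImageFrame}.
#' @export
simulatePhantom <- function(cfg, layout, noise = TRUE, supersample = 4L) {
  stopifnot(is(cfg, "ChainConfig"), is(layout, "PhantomLayout"))
  H <- cfg@frameShape[1L]; W <- cfg@frameShape[2L]
  a <- cfg@pixelPitch; s <- as.integer(supersample)
  dd <- layout@discs
  if (nrow(dd) && any(dd$cx - dd$radius < 0 | dd$cx + dd$radius > W |
                      dd$cy - dd$radius < 0 | dd$cy + dd$radius > H))
    stop("layout error: discs must lie inside the frame")
  for (p in layout@roiPairs) {
    for (r in p) if (r@x + r@width > W || r@y + r@height > H)
      stop("layout error: ROI exceeds the frame")
  }
  # transmission field on the sub-pixel grid (0-based pixel coordinates)
  xs <- (seq_len(W * s) - 0.5) / s
  ys <- (seq_len(H * s) - 0.5) / s
  Tr <- matrix(1, H * s, W * s)
  for (k in seq_len(nrow(dd))) {
    inside <- outer((ys - dd$cy[k])^2, (xs - dd$cx[k])^2, `+`) <=
      dd$radius[k]^2
    Tr[inside] <- Tr[inside] * (1 - dd$contrast[k])
  }
  if (cfg@blurSigma > 0) Tr <- blurPeriodic(Tr, cfg@blurSigma, a / s)
  meanCounts <- cfg@fluence * (a / s)^2 * blockSum(Tr, s)
  frame <- withSeed(subSeed(cfg@seed, 1L), {
    counts <- if (noise) matrix(rpoisCount(meanCounts), H, W) else meanCounts
    readout(counts, cfg, noise)
  })
  imageFrame(frame, a)
}

#' Closed-form MTF of the simulated chain
#'
#' Gaussian scintillator blur times the square pixel aperture:
#' exp(-2 pi^2 sigma^2 f^2) * |sinc(pi * pitch * f)|, equal to 1 at f = 0.
#'
#' @param cfg a \linkS4class{ChainConfig}.
#' @param f spatial frequencies, lp/mm (>= 0).
#' @return MTF values.
#' @export
theoreticalMTF <- function(cfg, f) {
  stopifnot(is(cfg, "ChainConfig"))
  if (any(f < 0)) stop("domain error: f must be >= 0")
  exp(-2 * pi^2 * cfg@blurSigma^2 * f^2) * abs(sinc(pi * cfg@pixelPitch * f))
}

#' Closed-form NNPS of the simulated chain
#'
#' Quantum term: the white photon shot-noise spectrum shaped by the squared
#' blur and aperture transfer functions, folded over the pixel sampling grid
#' (aliases within +/-2 replicas), divided by the detected fluence.
#' Electronic term: sigma_e^2 pitch^2 / mean^2, with mean =
#' gain x fluence x pitch^2. With no blur and no electronic noise this
#' reduces to the flat value 1/fluence (mm^2).
#'
#' @param cfg a \linkS4class{ChainConfig}.
#' @param f spatial frequencies along an axis, lp/mm, in [0, Nyquist].
#' @return NNPS values, mm^2.
#' @export
theoreticalNNPS <- function(cfg, f) {
  stopifnot(is(cfg, "ChainConfig"))
  a <- cfg@pixelPitch
  nyq <- 1 / (2 * a)
  if (any(f < 0 | f > nyq + 1e-9))
    stop("domain error: f must lie in [0, Nyquist = ", signif(nyq, 4), "]")
  mu <- cfg@gain * cfg@fluence * a^2
  if (mu == 0)
    stop("undefined-normalization error: zero mean signal")
  if (cfg@blurSigma == 0) {
    # no blur: the complete alias sum of the squared aperture spectrum is
    # exactly 1 at every frequency, so the quantum term is flat
    return(rep(1 / cfg@fluence, length(f)) +
             (cfg@electronicSigma * a)^2 / mu^2)
  }
  quantum <- 0
  for (k in -2:2) for (l in -2:2) {
    u <- f + k / a
    v <- l / a
    quantum <- quantum +
      exp(-4 * pi^2 * cfg@blurSigma^2 * (u^2 + v^2)) *
      sinc(pi * a * u)^2 * sinc(pi * a * v)^2
  }
  quantum / cfg@fluence + (cfg@electronicSigma * a)^2 / mu^2
}
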