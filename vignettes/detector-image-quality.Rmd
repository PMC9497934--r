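---
title: "Physical image-quality characterization of flat-panel detectors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physical image-quality characterization of flat-panel detectors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelIQ)
```

# Scope

panelIQ measures the three standard physical image-quality metrics of a
digital radiography flat panel — the presampled modulation transfer function
(MTF), the normalized noise power spectrum (NNPS) and the detective quantum
efficiency (DQE) — plus the phantom metrics CNR and COV, and provides a
restoration module (PSF synthesis from a measured MTF, adaptive denoising,
Wiener deconvolution). Because real measurements require an X-ray bench, the
package ships a forward simulator of the imaging chain whose MTF and NNPS are
known in closed form; every estimator is validated against those closed
forms, and users can validate modified parameter choices the same way.

# The simulated imaging chain

The model of an indirect-conversion (CsI(Tl) on a-Si TFT) panel has five
parameters (`chainConfig()`):

* detected photon fluence $q$ (photons/mm²) — either given directly or
  derived from a beam quality and air kerma as
  $q = \eta \, K_a \, \mathrm{SNR}^2_{in}/K_a$, with $\eta$ an absorbed
  fraction;
* isotropic Gaussian scintillator blur of standard deviation $\sigma$ (mm);
* a square pixel aperture of side $a$ equal to the pixel pitch;
* a linear gain $G$ (signal units per detected photon);
* additive Gaussian electronic noise of standard deviation $\sigma_e$ per
  pixel.

Its presampled MTF is
$$\mathrm{MTF}(f) = e^{-2\pi^2\sigma^2 f^2}\,
  \left|\mathrm{sinc}(\pi a f)\right|,$$
and its NNPS along an axis is
$$\mathrm{NNPS}(u) = \frac{1}{q}\sum_{k,l}
  e^{-4\pi^2\sigma^2\left(u_k^2+v_l^2\right)}
  \mathrm{sinc}^2(\pi a u_k)\,\mathrm{sinc}^2(\pi a v_l)
  \;+\; \frac{(\sigma_e a)^2}{\mu^2},
  \qquad u_k = u + k/a,\; v_l = l/a,\; \mu = G q a^2,$$
i.e. the white shot-noise spectrum shaped by the squared blur-and-aperture
transfer and folded over the sampling grid, plus a flat electronic term.
`theoreticalNNPS()` truncates the alias sum at $\pm 2$ replicas, except in
the blur-free case where the infinite aperture alias sum is exactly 1 at
every frequency, so the blur-free, electronics-free NNPS is exactly $1/q$;
the implementation special-cases this so the advertised white-noise value is
exact rather than 0.8% low.

Three rendering paths share this model:

* **Flat fields** (`simulateFlatField`). With blur, Poisson photons are drawn
  on a sub-pixel grid (`supersample` = 4 by default), blurred by a periodic
  FFT Gaussian, and aggregated over exact $s \times s$ pixel apertures — so
  the pixel-to-pixel noise correlation that the NNPS measures is physically
  present, not painted on. Counts with mean above 1000 use a Gaussian
  approximation (relative skewness there < 0.032).
* **Tilted edges** (`simulateEdgeImage`). The blurred step has a closed form
  (error function), and the pixel-aperture integral is evaluated by midpoint
  supersampling (8² points per pixel), giving an exact mean image; Poisson
  noise is then drawn **independently per pixel**. This is a deliberate
  approximation: blur-induced noise correlation is reproduced only in flat
  fields, where the NNPS is estimated. For the MTF the edge noise merely
  perturbs the ESF, and tests show the estimator recovers the closed forms
  from noisy edges regardless.
* **Phantoms** (`simulatePhantom`). Discs attenuate the fluence before blur
  and noise, with sub-pixel rendering of the disc boundary.

Determinism: every frame is drawn under a sub-seed
`(seed + 1000003 * frameIndex) mod (2^31 - 1)`, so frame $i$ is bit-identical
no matter how many frames are requested, and the caller's RNG stream is saved
and restored around every draw.

# Presampled MTF from a slanted edge

`measureMTF` follows the standard slanted-edge chain:

1. **Angle.** Each image row's mid-level crossing is found by linear
   interpolation between the two samples bracketing the 50% level (plateau
   levels from the 20% trimmed tails of the column means); a least-squares
   line through the crossings gives the tilt. Angles outside the 1.5–3°
   range recommended for presampled measurement raise a warning, not an
   error. A profile whose step is not significant against the row-noise
   estimate raises an `edge-not-found error`.
2. **Oversampled ESF.** Every pixel is projected onto the edge normal and
   binned at pitch/`oversample` (default 10). Bins at the record ends that
   receive fewer than half the median pixel count are trimmed: frame corners
   feed only a handful of pixels into the extreme bins, and under Poisson
   noise those bins otherwise host spurious |LSF| maxima. Interior empty
   bins are filled by linear interpolation.
3. **LSF, window, DFT.** The LSF is the central difference of the ESF. A
   Hann window spanning the record is centred on the LSF peak, which is
   located on a pixel-width moving average of |LSF| so a single noisy bin
   cannot steal the window centre. The record is zero-padded to a power of
   two (≥ 4096) before the FFT.
4. **Finite-difference correction.** The central difference of step $\Delta$
   has transfer $\sin(2\pi f\Delta)/(2\pi f\Delta)$; the spectrum magnitude
   is divided by it. (This is the mathematically correct transfer of the
   central difference; a plain two-point difference would instead need
   $\mathrm{sinc}(\pi f \Delta)$.)
5. The curve is normalized to 1 at $f = 0$ and reported on a uniform
   0.05 lp/mm grid up to Nyquist $= 1/(2a)$.

Validation: a sharp simulated edge returns $|\mathrm{sinc}(\pi a f)|$ with
error < 0.01 at Nyquist (2/π ≈ 0.6366); a Gaussian-blurred edge matches the
closed form within 2% absolute up to 0.8 × Nyquist; the estimate is invariant
to image scaling, edge polarity, and tilt angle.

# NNPS from a flat-field series

`nnps2D` implements the standard half-overlapping-ROI estimator:

* the central 1024² region of each frame is selected (smaller frames fall
  back to the largest centred square whose side is a multiple of the ROI
  side, with a warning);
* the region is tiled by 50%-overlapping ROIs — $(2\,R/r - 1)^2$ per frame,
  i.e. 49 ROIs of side 256 or 225 of side 128 in a 1024 region;
* each ROI is detrended by a least-squares 2-D polynomial surface
  (`detrendOrder` 0, 1 or 2; default 2) to remove exposure shading;
* the mean squared-magnitude periodogram is scaled by $a^2/N_{pix}$ (units
  mm²) and divided by the squared grand-mean signal, so a global gain factor
  cancels exactly.

`nnps1D` reduces the 2-D spectrum either axially — for each on-axis
frequency, the mean of the seven rows/columns on each side of the axis,
excluding the axis itself, both orientations averaged — or radially, in
annuli seven frequency bins wide excluding DC.

Two estimator biases are known, deliberate and documented rather than hidden:

* **Detrending bias.** Order-2 detrending removes part of the true noise
  power in the lowest few frequency bins (≈ −14% observed at the lowest
  axial bins on white noise). It is kept as the default because flat fields
  from real detectors carry low-order exposure shading that would otherwise
  leak into exactly those bins; validation tests that compare against the
  flat closed form use `detrendOrder = 0`.
* **Finite-window (Fejér) leakage.** The expected value of a rectangular-
  window ROI periodogram is the true spectrum convolved with the Fejér
  kernel. For steep (strongly blurred) spectra this inflates high-frequency
  bins — by up to ~2× at Nyquist for σ = 0.08 mm and 128-pixel ROIs — and
  slightly deflates the low-frequency peak; the effect halves when the ROI
  side doubles. This is a property of every periodogram-based NNPS
  estimator, not a bug, so the test suite validates blurred chains against a
  *windowed expectation oracle*: true spectrum → pixel covariance → Bartlett
  triangle weighting → expected periodogram. For white spectra (no blur) the
  leakage is identically zero, which is why the quantitative NNPS/DQE level
  checks run on blur-free chains.

Validation: white noise with known $\sigma^2 a^2/\mu^2$ is recovered within
3 relative standard errors per axial bin; the NNPS integral obeys the
Parseval identity against the mean detrended ROI variance to machine
precision; axial and radial reductions agree for isotropic fields.

# DQE

$$\mathrm{DQE}(f) = \frac{\mathrm{MTF}^2(f)}{\Phi\cdot\mathrm{NNPS}(f)},
\qquad \Phi = K_a \cdot \mathrm{SNR}^2_{in}/K_a .$$

The NNPS enters to the first power — the dimensionally consistent form
(NNPS in mm², Φ in mm⁻²). `computeDQE` resamples both curves by linear
interpolation onto the coarser of the two frequency grids restricted to
their common range (no extrapolation), refuses zero NNPS bins with an error
naming the frequency, and reports values unclipped, warning when sampling
noise pushes a bin above 1. A blur-free, electronics-free simulated chain
driven by the registry fluence yields DQE(f→0) = 1 within 5%, and the DQE is
exactly invariant under the chain gain when electronic noise is zero.

# Registries

`beamQuality()` returns the standardized RQA beam constants (tube voltage,
added aluminium filtration, half-value layer, SNR² per air kerma); the 2015
protocol revision is the default and the superseded 2003 constants are
retained under `protocol = "2003"`. `detectorSpec()` returns the physical
specifications of three registered CsI(Tl) panels differing mainly in
scintillator thickness and pixel pitch. Lookups fold case, whitespace and
hyphens, fail loudly with the list of registered keys, and can be redirected
at user YAML files with the same schema.

# Illustrative detector presets

`illustrativePreset()` maps each registered detector to a chain
configuration. The pixel pitch comes from the specification registry; the
blur sigma, absorbed fraction, gain and electronic noise are **illustrative**
(the physical panels' values are not public), chosen once so the classic
scintillator-thickness trade-off has its expected qualitative signature: the
standard-thickness panel resolves best (highest MTF), while the thick,
fine-pitch panel absorbs more photons and therefore has the lowest NNPS and
the highest DQE at every frequency. The acceptance suite asserts exactly
those orderings — the presets are not calibrated to reproduce any measured
curve.

# Restoration

`psfFromMTF` assembles a radially symmetric transfer magnitude from a 1-D
MTF (linear interpolation on the curve; log-linear, never-upward extension
beyond its last sample), inverse-transforms it on a grid at least 8× the
requested support, crops, clips negative ringing at zero and renormalizes to
unit sum. `denoiseAdaptive` is a local minimum-mean-square (Wiener-type)
filter: $\hat x = m + \max(0, v - v_n)/\max(v, v_n)\,(x - m)$ with local
mean/variance $m, v$ over an odd window and noise variance $v_n$ (median
local variance under `"auto"`). `wienerDeconvolve` applies
$H/(H^2 + \mathrm{nsr})$ in the frequency domain with the zero-frequency
gain pinned to 1 (mean preservation) and symmetric padding (default 32 px)
against wrap-around. Deconvolution is high-pass, so the intended workflow is
denoise first, then deconvolve; tests confirm the staged order has lower
RMSE than deconvolving alone, and that a noiseless degrade–restore round
trip has interior RMSE below 1% of the image range.

# Problem sizes and runtime

The sizes used throughout the tests are the package's own choice, set to
exercise every code path in seconds on one CPU: 512² frames for MTF and DQE
oracle checks, 256² frames with 64-pixel ROIs for NNPS statistics (the
1024²-region / 256-ROI geometry is exercised for counts), 4–8 flat frames
per series. Production-scale inputs (≥ 10 frames of 3072² at 139 µm) run
through identical code; only the ROI bookkeeping grows.

# Limitations

* The simulator's blur is a single isotropic Gaussian; real scintillator
  optics have longer tails (light channeling, K-fluorescence).
* Edge and phantom images carry uncorrelated quantum noise (see above);
  only flat fields model blur-induced noise correlation.
* The NNPS estimator inherits the finite-window leakage of all periodogram
  methods; compare against the windowed oracle, not the infinite-window
  spectrum, when validating steep spectra.
* Beam registries carry the standardized constants only; no spectral
  simulation is attempted.
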