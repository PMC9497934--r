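#' @import methods
NULL

#' Standardized X-ray beam quality
#'
#' An RQA beam quality as used for detector characterization: a heavily
#' filtered spectrum summarized by its half-value layer and its squared
#' signal-to-noise ratio per unit air kerma, which doubles as the photon
#' fluence per air kerma ratio used in the DQE.
#'
#' @slot name beam quality identifier, e.g. \code{"RQA5"}.
#' @slot tubeVoltage tube voltage, kV.
#' @slot addedFiltration added aluminium filtration, mm Al.
#' @slot halfValueLayer half-value layer, mm Al.
#' @slot snr2PerKerma squared SNR per air kerma, 1/(mm^2 uGy); numerically
#'   equal to the photon fluence (mm^-2) produced by 1 uGy air kerma.
#' @slot protocol protocol revision the constants belong to ("2015" or "2003").
#'
#' @export
setClass("BeamQuality",
  representation(
    name = "character",
    tubeVoltage = "numeric",
    addedFiltration = "numeric",
    halfValueLayer = "numeric",
    snr2PerKerma = "numeric",
    protocol = "character"
  )
)

setValidity("BeamQuality", function(object) {
  num <- c(object@tubeVoltage, object@addedFiltration,
           object@halfValueLayer, object@snr2PerKerma)
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (any(!is.finite(num)) || any(num <= 0))
    return("all numeric beam-quality fields must be finite and > 0")
  TRUE
})

#' Flat-panel detector specification
#'
#' Physical specification of an indirect-conversion (CsI(Tl) scintillator on
#' a-Si TFT) flat-panel detector.
#'
#' @slot name detector model identifier.
#' @slot scintillatorThicknessFactor scintillator thickness as a multiple of
#'   the standard-thickness reference panel (dimensionless, >= 1).
#' @slot pixelPitch pixel pitch, micrometres.
#' @slot matrix full pixel matrix, c(rows, cols).
#' @slot detectionArea active detection area, c(rows, cols) pixels.
#' @slot weight detector weight, kg.
#'
#' @export
setClass("DetectorSpec",
  representation(
    name = "character",
    scintillatorThicknessFactor = "numeric",
    pixelPitch = "numeric",
    matrix = "integer",
    detectionArea = "integer",
    weight = "numeric"
  )
)

setValidity("DetectorSpec", function(object) {
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@scintillatorThicknessFactor < 1)
    return("scintillatorThicknessFactor must be >= 1")
  if (length(object@matrix) != 2L || length(object@detectionArea) != 2L)
    return("matrix and detectionArea must each have two dimensions")
  if (any(object@matrix < object@detectionArea))
    return("matrix dimensions must be >= detectionArea dimensions")
  TRUE
})

#' A 2-D radiographic frame
#'
#' A single grayscale frame of linearized detector signal together with the
#' pixel pitch that fixes its spatial-frequency axis. Rows index the y
#' (vertical) direction, columns the x (horizontal) direction.
#'
#' @slot data numeric matrix of pixel values (linear detector signal).
#' @slot pixelPitch pixel pitch, mm.
#'
#' @export
setClass("ImageFrame",
  representation(data = "matrix", pixelPitch = "numeric")
)

setValidity("ImageFrame", function(object) {
  if (!is.numeric(object@data)) return("frame data must be numeric")
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    return("pixelPitch must be a single positive number (mm)")
  TRUE
})

#' Imaging-chain simulator configuration
#'
#' Ground-truth parameters of the forward model of an indirect-conversion
#' flat panel: Poisson quantum noise at a given detected photon fluence,
#' isotropic Gaussian scintillator blur, square pixel-aperture integration,
#' linear system gain and additive Gaussian electronic noise.
#'
#' @slot fluence detected photon fluence, photons/mm^2.
#' @slot pixelPitch pixel pitch, mm.
#' @slot blurSigma standard deviation of the Gaussian scintillator point
#'   spread function, mm.
#' @slot gain output signal units per detected photon.
#' @slot electronicSigma standard deviation of additive electronic noise,
#'   output signal units per pixel.
#' @slot frameShape frame dimensions, c(rows, cols).
#' @slot seed master random seed; identical configuration and seed give
#'   bit-identical frames.
#'
#' @export
setClass("ChainConfig",
  representation(
    fluence = "numeric",
    pixelPitch = "numeric",
    blurSigma = "numeric",
    gain = "numeric",
    electronicSigma = "numeric",
    frameShape = "integer",
    seed = "integer"
  )
)

setValidity("ChainConfig", function(object) {
  if (object@fluence < 0) return("fluence must be >= 0")
  if (object@pixelPitch <= 0) return("pixelPitch must be > 0")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  if (object@gain <= 0) return("gain must be > 0")
  if (object@electronicSigma < 0) return("electronicSigma must be >= 0")
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    return("frameShape must be two positive integers")
  TRUE
})

#' Rectangular region of interest
#'
#' ROI coordinates are 0-based with the origin at the top-left pixel and
#' half-open extents [x, x+width) x [y, y+height); x indexes columns and y
#' indexes rows.
#'
#' @slot x,y 0-based pixel origin (column, row).
#' @slot width,height extent in pixels.
#'
#' @export
setClass("ROIRect",
  representation(x = "integer", y = "integer",
                 width = "integer", height = "integer")
)

setValidity("ROIRect", function(object) {
  if (object@x < 0L || object@y < 0L) return("ROI origin must be >= 0")
  if (object@width < 1L || object@height < 1L)
    return("ROI width and height must be >= 1")
  if (object@width * object@height < 4L)
    return("ROI area must be at least 4 pixels")
  TRUE
})

#' Contrast phantom layout
#'
#' Disc-on-background contrast phantom: each disc attenuates the incident
#' fluence by its contrast fraction. ROI pairs associate a target ROI inside
#' a disc with a background ROI for CNR evaluation.
#'
#' @slot discs data.frame with columns \code{cx, cy} (0-based pixel centre),
#'   \code{radius} (pixels) and \code{contrast} (fraction in (0, 1]).
#' @slot roiPairs list of \code{list(target=, background=)} ROIRect pairs.
#'
#' @export
setClass("PhantomLayout",
  representation(discs = "data.frame", roiPairs = "list")
)

setValidity("PhantomLayout", function(object) {
  need <- c("cx", "cy", "radius", "contrast")
  if (!all(need %in% names(object@discs)))
    return("discs must have columns cx, cy, radius, contrast")
  if (any(object@discs$radius <= 0)) return("disc radius must be > 0")
  if (any(object@discs$contrast <= 0 | object@discs$contrast > 1))
    return("disc contrast must be in (0, 1]")
  for (p in object@roiPairs) {
    if (!all(c("target", "background") %in% names(p)))
      return("each ROI pair needs 'target' and 'background'")
    if (roiOverlaps(p$target, p$background))
      return("target and background ROIs of a pair must not overlap")
  }
  TRUE
})

#' Oversampled edge spread function
#'
#' ESF produced by projecting pixels of a tilted-edge image onto the
#' edge-normal axis and binning at a sub-pixel width.
#'
#' @slot positions bin centres along the edge normal, mm; strictly
#'   increasing with uniform spacing equal to \code{binWidth}.
#' @slot values mean signal per bin.
#' @slot binWidth bin width, mm (pixel pitch / oversampling factor).
#' @slot pixelPitch pitch of the source image, mm (fixes the Nyquist
#'   frequency of the reported MTF).
#'
#' @export
setClass("OversampledESF",
  representation(positions = "numeric", values = "numeric",
                 binWidth = "numeric", pixelPitch = "numeric")
)

setValidity("OversampledESF", function(object) {
  if (length(object@positions) != length(object@values))
    return("positions and values must have equal length")
  if (object@binWidth <= 0) return("binWidth must be > 0")
  d <- diff(object@positions)
  if (any(d <= 0)) return("positions must be strictly increasing")
  if (any(abs(d - object@binWidth) > 1e-6 * object@binWidth))
    return("positions must be uniformly spaced at binWidth")
  if (any(!is.finite(object@values)))
    return("ESF has non-finite bins (empty bins must be filled)")
  TRUE
})

#' Sampled curves over spatial frequency
#'
#' \code{FrequencyCurve} is the common representation of a 1-D function of
#' spatial frequency (lp/mm); \code{MTFCurve}, \code{NNPSCurve} and
#' \code{DQECurve} specialize it for the three detector metrics.
#'
#' @slot frequencies spatial frequencies, lp/mm, ascending.
#' @slot values metric values at those frequencies.
#'
#' @export
setClass("FrequencyCurve",
  representation(frequencies = "numeric", values = "numeric")
)

setValidity("FrequencyCurve", function(object) {
  if (length(object@frequencies) != length(object@values))
    return("frequencies and values must have equal length")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    return("frequencies must be strictly ascending")
  if (any(object@frequencies < 0)) return("frequencies must be >= 0")
  TRUE
})

#' @rdname FrequencyCurve-class
#' @slot nyquist detector Nyquist frequency, lp/mm.
#' @export
setClass("MTFCurve", contains = "FrequencyCurve",
  representation(nyquist = "numeric")
)

setValidity("MTFCurve", function(object) {
  if (object@nyquist <= 0) return("nyquist must be > 0")
  if (length(object@values) &&
      abs(object@frequencies[1L]) < 1e-12 &&
      abs(object@values[1L] - 1) > 1e-9)
    return("MTF must equal 1 at zero frequency")
  TRUE
})

#' @rdname FrequencyCurve-class
#' @slot nRois number of regions of interest averaged into the estimate.
#' @export
setClass("NNPSCurve", contains = "FrequencyCurve",
  representation(nRois = "integer")
)

setValidity("NNPSCurve", function(object) {
  if (any(object@values < 0)) return("NNPS values must be >= 0")
  TRUE
})

#' @rdname FrequencyCurve-class
#' @slot kerma air kerma the DQE refers to, uGy.
#' @slot beam beam quality name.
#' @export
setClass("DQECurve", contains = "FrequencyCurve",
  representation(kerma = "numeric", beam = "character")
)

setValidity("DQECurve", function(object) {
  if (any(object@values < 0)) return("DQE values must be >= 0")
  if (object@kerma <= 0) return("kerma must be > 0")
  TRUE
})

#' Two-dimensional noise power spectrum
#'
#' NNPS on the full (u, v) frequency grid of the analysis ROI, in standard
#' DFT ordering (frequency k/(side * pitch) at index k + 1, negative
#' frequencies wrapped).
#'
#' @slot values non-negative NNPS values, mm^2, side x side.
#' @slot frequencyStep frequency grid step, lp/mm = 1/(side * pitch).
#' @slot nRois number of ROIs averaged.
#'
#' @export
setClass("NNPS2D",
  representation(values = "matrix", frequencyStep = "numeric",
                 nRois = "integer")
)

setValidity("NNPS2D", function(object) {
  if (nrow(object@values) != ncol(object@values))
    return("NNPS grid must be square")
  if (any(object@values < 0)) return("NNPS values must be >= 0")
  if (object@frequencyStep <= 0) return("frequencyStep must be > 0")
  TRUE
})

#' Linear degradation model
#'
#' The degradation of a radiograph as a shift-invariant blur plus additive
#' noise: observed = PSF ** clean + n, with ** denoting 2-D convolution.
#'
#' @slot psf non-negative 2-D kernel with unit sum.
#' @slot noiseSigma standard deviation of the additive Gaussian noise,
#'   signal units.
#'
#' @export
setClass("DegradationModel",
  representation(psf = "matrix", noiseSigma = "numeric")
)

setValidity("DegradationModel", function(object) {
  if (any(object@psf < 0)) return("psf values must be >= 0")
  if (abs(sum(object@psf) - 1) > 1e-6)
    return("psf must sum to 1 (within 1e-6)")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})
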