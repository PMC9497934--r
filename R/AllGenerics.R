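# Constructors, accessors and show methods for the core classes.

#' Construct an ImageFrame
#'
#' @param data numeric matrix of linear detector signal (rows = y, cols = x).
#' @param pixelPitch pixel pitch, mm.
#' @return An \linkS4class{ImageFrame}.
#' @examples
#' f <- imageFrame(matrix(100, 32, 32), pixelPitch = 0.1)
#' nyquistFrequency(f)
#' @export
imageFrame <- function(data, pixelPitch) {
  new("ImageFrame", data = data, pixelPitch = as.numeric(pixelPitch))
}

#' Construct a rectangular ROI
#'
#' Coordinates are 0-based with a top-left origin; extents are half-open,
#' so \code{roiRect(0, 0, 10, 10)} covers pixel columns 0..9 and rows 0..9.
#'
#' @param x,y 0-based origin (column, row).
#' @param width,height extent in pixels.
#' @return An \linkS4class{ROIRect}.
#' @export
roiRect <- function(x, y, width, height) {
  new("ROIRect", x = as.integer(x), y = as.integer(y),
      width = as.integer(width), height = as.integer(height))
}

#' @describeIn imageFrame Pixel data of a frame.
#' @param object an \code{ImageFrame}.
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))

#' @rdname imageFrame
#' @export
setMethod("frameData", "ImageFrame", function(object) object@data)

#' Pixel pitch accessor
#'
#' @param object an object carrying a pixel pitch (mm).
#' @return Pixel pitch in mm.
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ImageFrame", function(object) object@pixelPitch)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "ChainConfig", function(object) object@pixelPitch)

#' @rdname pixelPitch
#' @export
setMethod("pixelPitch", "OversampledESF", function(object) object@pixelPitch)

#' Frequency axis of a curve
#'
#' @param object a \code{FrequencyCurve}.
#' @return Numeric vector of spatial frequencies, lp/mm.
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname frequencies
#' @export
setMethod("frequencies", "FrequencyCurve", function(object) object@frequencies)

#' Values of a curve
#'
#' @param object a \code{FrequencyCurve}.
#' @return Numeric vector of metric values.
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))

#' @rdname curveValues
#' @export
setMethod("curveValues", "FrequencyCurve", function(object) object@values)

#' Nyquist frequency
#'
#' The highest representable spatial frequency, 1/(2 x pixel pitch).
#'
#' @param object an \code{ImageFrame}, \code{ChainConfig} or \code{MTFCurve}.
#' @return Nyquist frequency, lp/mm.
#' @export
setGeneric("nyquistFrequency",
           function(object) standardGeneric("nyquistFrequency"))

#' @rdname nyquistFrequency
#' @export
setMethod("nyquistFrequency", "ImageFrame",
          function(object) 1 / (2 * object@pixelPitch))

#' @rdname nyquistFrequency
#' @export
setMethod("nyquistFrequency", "ChainConfig",
          function(object) 1 / (2 * object@pixelPitch))

#' @rdname nyquistFrequency
#' @export
setMethod("nyquistFrequency", "MTFCurve", function(object) object@nyquist)

setMethod("show", "ImageFrame", function(object) {
  cat(sprintf("ImageFrame: %d x %d pixels, pitch %.4g mm (Nyquist %.3g lp/mm)\n",
              nrow(object@data), ncol(object@data), object@pixelPitch,
              1 / (2 * object@pixelPitch)))
  cat(sprintf("  signal range [%.4g, %.4g], mean %.4g\n",
              min(object@data), max(object@data), mean(object@data)))
})

setMethod("show", "BeamQuality", function(object) {
  cat(sprintf("BeamQuality %s (IEC %s): %g kV + %g mm Al, HVL %g mm Al\n",
              object@name, object@protocol, object@tubeVoltage,
              object@addedFiltration, object@halfValueLayer))
  cat(sprintf("  SNR^2 per air kerma: %g 1/(mm^2 uGy)\n", object@snr2PerKerma))
})

setMethod("show", "DetectorSpec", function(object) {
  cat(sprintf("DetectorSpec %s: CsI(Tl) x%.1f, pitch %g um, matrix %d x %d, %g kg\n",
              object@name, object@scintillatorThicknessFactor,
              object@pixelPitch, object@matrix[1L], object@matrix[2L],
              object@weight))
})

setMethod("show", "ChainConfig", function(object) {
  cat(sprintf("ChainConfig: %d x %d frame, pitch %g mm\n",
              object@frameShape[1L], object@frameShape[2L], object@pixelPitch))
  cat(sprintf("  fluence %g /mm^2, blur sigma %g mm, gain %g, electronic sigma %g, seed %d\n",
              object@fluence, object@blurSigma, object@gain,
              object@electronicSigma, object@seed))
})

setMethod("show", "FrequencyCurve", function(object) {
  cat(sprintf("%s: %d samples, f in [%.3g, %.3g] lp/mm\n",
              class(object), length(object@frequencies),
              if (length(object@frequencies)) min(object@frequencies) else NA,
              if (length(object@frequencies)) max(object@frequencies) else NA))
})

setMethod("show", "ROIRect", function(object) {
  cat(sprintf("ROIRect: origin (%d, %d), %d x %d pixels\n",
              object@x, object@y, object@width, object@height))
})

setMethod("show", "NNPS2D", function(object) {
  cat(sprintf("NNPS2D: %d x %d grid, step %.4g lp/mm, %d ROIs averaged\n",
              nrow(object@values), ncol(object@values),
              object@frequencyStep, object@nRois))
})

setMethod("show", "DegradationModel", function(object) {
  cat(sprintf("DegradationModel: %d x %d PSF, noise sigma %g\n",
              nrow(object@psf), ncol(object@psf), object@noiseSigma))
})

# -- internal helpers shared across modules ---------------------------------

# Evaluate a function with a temporary RNG seed, restoring the caller's
# random stream afterwards. Keeps simulator calls from perturbing user code.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unnormalized sinc: sin(x)/x with sinc(0) = 1
sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)

# extract an ROI submatrix from a frame (0-based ROI convention)
roiSubmatrix <- function(frame, roi) {
  dat <- frame@data
  if (roi@x + roi@width > ncol(dat) || roi@y + roi@height > nrow(dat))
    stop("geometry error: ROI [", roi@x, ",", roi@y, ",", roi@width, ",",
         roi@height, "] exceeds the ", nrow(dat), " x ", ncol(dat), " frame")
  dat[(roi@y + 1L):(roi@y + roi@height), (roi@x + 1L):(roi@x + roi@width),
      drop = FALSE]
}
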