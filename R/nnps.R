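# Normalized noise power spectrum from a flat-field series: central-region
# selection, half-overlapping ROI tiling, per-ROI polynomial detrending,
# periodogram averaging with the pitch^2 / Npix scaling that yields mm^2
# units, normalization by the squared mean signal, and seven-bin axial and
# radial reductions to 1-D curves.

# 0-based offsets of half-overlapping tiles of side `side` inside `region`
tileOffsets <- function(region, side) {
  seq.int(0L, region - side, by = side %/% 2L)
}

# largest centred square region with side a multiple of roiSide
centralRegion <- function(frameDim, roiSide, regionSide) {
  side <- min(regionSide, min(frameDim))
  side <- (side %/% roiSide) * roiSide
  if (side < roiSide)
    stop("insufficient-data error: frame smaller than one ", roiSide,
         " x ", roiSide, " ROI")
  if (side < regionSide)
    warning("frame smaller than the ", regionSide, "^2 analysis region; ",
            "using the largest centred ", side, "^2 square instead")
  side
}

#' Extract half-overlapping ROIs from flat-field frames
#'
#' Selects the central homogeneous square region (1024 x 1024 pixels by
#' default; for smaller frames, the largest centred square whose side is a
#' multiple of the ROI side, with a warning) and tiles it with 50% overlap in
#' both axes, giving (2 * region/roiSide - 1)^2 ROIs per frame.
#'
#' @param frames list of \linkS4class{ImageFrame}s sharing shape and pitch.
#' @param roiSide ROI side in pixels, 128 or 256.
#' @param regionSide analysis region side, pixels (default 1024).
#' @return List of numeric matrices (roiSide x roiSide), frame-major order.
#' @export
extractROIs <- function(frames, roiSide = 256L, regionSide = 1024L) {
  stopifnot(length(frames) >= 1L, roiSide %in% c(128L, 256L) ||
              roiSide >= 8L)
  dims <- vapply(frames, function(f) dim(f@data), integer(2))
  if (any(dims != dims[, 1L]))
    stop("frames must share the same shape")
  side <- centralRegion(dims[, 1L], roiSide, regionSide)
  r0 <- (dims[1L, 1L] - side) %/% 2L
  c0 <- (dims[2L, 1L] - side) %/% 2L
  offs <- tileOffsets(side, roiSide)
  out <- vector("list", length(frames) * length(offs)^2)
  k <- 0L
  for (f in frames) {
    reg <- f@data[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
    for (oy in offs) for (ox in offs) {
      k <- k + 1L
      out[[k]] <- reg[(oy + 1L):(oy + roiSide), (ox + 1L):(ox + roiSide)]
    }
  }
  out
}

# design matrix of a 2-D polynomial surface on an n x n grid, coords in [-1,1]
polyBasis <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(x, n, n)
  cols <- list(rep(1, n * n))
  if (order >= 1L) cols <- c(cols, list(as.vector(X), as.vector(Y)))
  if (order >= 2L) cols <- c(cols, list(as.vector(X)^2,
                                        as.vector(X) * as.vector(Y),
                                        as.vector(Y)^2))
  do.call(cbind, cols)
}

#' Remove a low-order trend surface from an ROI
#'
#' Subtracts the least-squares 2-D polynomial surface of the given order
#' (0 = mean, 1 = plane, 2 = quadratic). The residual has zero mean to
#' machine precision; order 2 removes low-frequency exposure shading without
#' biasing mid frequencies.
#'
#' @param roi numeric matrix.
#' @param order polynomial order, 0, 1 or 2.
#' @param basis optional precomputed design matrix (internal reuse).
#' @return Residual matrix of the same shape.
#' @export
detrendROI <- function(roi, order = 2L, basis = NULL) {
  stopifnot(order %in% 0:2)
  if (is.null(basis)) basis <- polyBasis(nrow(roi), order)
  y <- as.vector(roi)
  coef <- solve(crossprod(basis), crossprod(basis, y))
  matrix(y - basis %*% coef, nrow(roi))
}

#' Two-dimensional NNPS of a flat-field series
#'
#' Mean periodogram of the detrended half-overlapping ROIs, scaled by
#' pitch^2 / (ROI pixel count) so the values carry mm^2 units, divided by the
#' squared grand-mean signal of the analysis region. Gain cancels through the
#' normalization.
#'
#' @param frames list of >= 2 \linkS4class{ImageFrame}s (10 flat frames is
#'   the standard series).
#' @param roiSide ROI side, 128 or 256 pixels (default 256).
#' @param detrendOrder polynomial detrending order (default 2; 0 gives plain
#'   mean subtraction).
#' @param regionSide analysis region side (default 1024).
#' @return An \linkS4class{NNPS2D} in standard DFT ordering.
#' @export
nnps2D <- function(frames, roiSide = 256L, detrendOrder = 2L,
                   regionSide = 1024L) {
  if (length(frames) < 2L)
    stop("nnps requires at least 2 flat-field frames")
  pitches <- vapply(frames, function(f) f@pixelPitch, numeric(1))
  if (any(abs(pitches - pitches[1L]) > 1e-12))
    stop("frames must share the same pixel pitch")
  a <- pitches[1L]
  dims <- vapply(frames, function(f) dim(f@data), integer(2))
  if (any(dims != dims[, 1L])) stop("frames must share the same shape")
  side <- centralRegion(dims[, 1L], roiSide, regionSide)
  r0 <- (dims[1L, 1L] - side) %/% 2L
  c0 <- (dims[2L, 1L] - side) %/% 2L
  offs <- tileOffsets(side, roiSide)
  basis <- polyBasis(roiSide, detrendOrder)
  gram <- solve(crossprod(basis))
  acc <- matrix(0, roiSide, roiSide)
  sbar <- 0
  nroi <- 0L
  for (f in frames) {
    reg <- f@data[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side), drop = FALSE]
    sbar <- sbar + mean(reg)
    for (oy in offs) for (ox in offs) {
      roi <- reg[(oy + 1L):(oy + roiSide), (ox + 1L):(ox + roiSide)]
      y <- as.vector(roi)
      res <- y - basis %*% (gram %*% crossprod(basis, y))
      acc <- acc + Mod(stats::fft(matrix(res, roiSide)))^2
      nroi <- nroi + 1L
    }
  }
  sbar <- sbar / length(frames)
  if (sbar == 0)
    stop("undefined-normalization error: zero mean signal")
  vals <- acc / nroi * a^2 / roiSide^2 / sbar^2
  new("NNPS2D", values = vals, frequencyStep = 1 / (roiSide * a),
      nRois = nroi)
}

#' Reduce a 2-D NNPS to a 1-D curve
#'
#' Axial mode: for each along-axis frequency, average the seven rows/columns
#' on each side of the frequency axis, excluding the axis itself; both axis
#' orientations are averaged (the simulated chain is isotropic). Radial mode:
#' average in annuli seven frequency bins wide, excluding the zero-frequency
#' bin.
#'
#' @param spec2d an \linkS4class{NNPS2D}.
#' @param mode \code{"axial"} or \code{"radial"}.
#' @return An \linkS4class{NNPSCurve} up to the Nyquist frequency.
#' @export
nnps1D <- function(spec2d, mode = c("axial", "radial")) {
  mode <- match.arg(mode)
  V <- spec2d@values
  L <- nrow(V)
  df <- spec2d@frequencyStep
  half <- L %/% 2L
  if (mode == "axial") {
    offs <- c(2:8, L - (0:6))          # +/- 1..7 bins off the axis
    freqs <- (0:half) * df
    vals <- vapply(0:half, function(k) {
      i <- k + 1L
      mean(c(V[i, offs], V[offs, i]))
    }, numeric(1))
  } else {
    kk <- c(0:half, -(half - 1L):-1L)  # DFT frequency indices
    R <- sqrt(outer(kk^2, kk^2, `+`)) * df
    width <- 7 * df
    nb <- floor((half * df) / width)
    freqs <- (seq_len(nb) - 0.5) * width
    vals <- vapply(seq_len(nb), function(j) {
      sel <- R > (j - 1) * width & R <= j * width & R > 0
      mean(V[sel])
    }, numeric(1))
  }
  new("NNPSCurve", frequencies = freqs, values = pmax(vals, 0),
      nRois = spec2d@nRois)
}

#' Measure the 1-D NNPS of a flat-field series
#'
#' Convenience wrapper around \code{\link{nnps2D}} and \code{\link{nnps1D}}.
#'
#' @inheritParams nnps2D
#' @inheritParams nnps1D
#' @return An \linkS4class{NNPSCurve}.
#' @export
measureNNPS <- function(frames, roiSide = 256L, detrendOrder = 2L,
                        regionSide = 1024L, mode = "axial") {
  nnps1D(nnps2D(frames, roiSide, detrendOrder, regionSide), mode)
}
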