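# Phantom quality metrics over rectangular ROIs: contrast-to-noise ratio
# between a target and a background ROI, and coefficient of variation within
# a single ROI.

# TRUE when two ROIs share any pixel (half-open extents)
roiOverlaps <- function(a, b) {
  a@x < b@x + b@width && b@x < a@x + a@width &&
    a@y < b@y + b@height && b@y < a@y + a@height
}

#' Mean and standard deviation of an ROI
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param roi an \linkS4class{ROIRect} fully inside the frame.
#' @param unbiased use the sample (n - 1) standard deviation (default TRUE;
#'   FALSE gives the n denominator).
#' @return List with \code{mean}, \code{sd} and \code{n} (pixel count).
#' @export
roiStats <- function(image, roi, unbiased = TRUE) {
  stopifnot(is(image, "ImageFrame"), is(roi, "ROIRect"))
  px <- as.vector(roiSubmatrix(image, roi))
  n <- length(px)
  s <- stats::sd(px)
  if (!unbiased) s <- s * sqrt((n - 1) / n)
  list(mean = mean(px), sd = s, n = n)
}

#' Contrast-to-noise ratio between two ROIs
#'
#' CNR = |mean_A - mean_B| / sqrt(sd_A^2 + sd_B^2); the absolute mean
#' difference over the root-sum-square of the two standard deviations.
#' Invariant under positive scaling and additive offsets of the image.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param roiA target \linkS4class{ROIRect}.
#' @param roiB background \linkS4class{ROIRect}.
#' @inheritParams roiStats
#' @return CNR, dimensionless.
#' @export
computeCNR <- function(image, roiA, roiB, unbiased = TRUE) {
  a <- roiStats(image, roiA, unbiased)
  b <- roiStats(image, roiB, unbiased)
  den <- sqrt(a$sd^2 + b$sd^2)
  if (den == 0) {
    if (a$mean == b$mean) return(0)
    stop("undefined-CNR error: both ROI standard deviations are zero")
  }
  abs(a$mean - b$mean) / den
}

#' Coefficient of variation of an ROI
#'
#' COV = sd / mean. Invariant under positive scaling, but not under additive
#' offsets (the mean shifts while the sd does not).
#'
#' @inheritParams computeCNR
#' @param roi an \linkS4class{ROIRect}.
#' @return COV, dimensionless.
#' @export
computeCOV <- function(image, roi, unbiased = TRUE) {
  s <- roiStats(image, roi, unbiased)
  if (s$mean == 0)
    stop("undefined-COV error: ROI mean is zero")
  s$sd / s$mean
}
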