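# Presampled MTF from a tilted-edge image: estimate the edge angle from
# per-row mid-level crossings, project pixels onto the edge normal into
# sub-pixel bins (oversampled ESF), differentiate to the LSF, window, Fourier
# transform, correct the finite-difference transfer and normalize at f = 0.

# Per-row mid-level crossings of a nearly vertical edge. Returns fractional
# column positions (1-based) or NA where no crossing is found.
edgeCrossings <- function(sub) {
  p <- colMeans(sub)
  lo <- mean(sort(p)[seq_len(max(1L, floor(length(p) * 0.2)))])
  hi <- mean(sort(p, decreasing = TRUE)[seq_len(max(1L, floor(length(p) * 0.2)))])
  mid <- (lo + hi) / 2
  noise <- stats::sd(diff(p)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if ((hi - lo) <= max(1e-12, 10 * noise))
    stop("edge-not-found error: no significant edge step in the ROI")
  pol <- if (mean(p[seq_len(max(1L, length(p) %/% 10))]) <
             mean(rev(p)[seq_len(max(1L, length(p) %/% 10))])) 1 else -1
  crossOne <- function(v) {
    w <- pol * v; m <- pol * mid
    below <- w < m
    cand <- which(below[-length(w)] & !below[-1L])
    if (!length(cand)) return(NA_real_)
    slopes <- w[cand + 1L] - w[cand]
    i <- cand[which.max(slopes)]
    i + (m - w[i]) / (w[i + 1L] - w[i])
  }
  xbar <- crossOne(p)
  if (is.na(xbar))
    stop("edge-not-found error: column-mean profile never crosses mid level")
  halfwin <- nrow(sub) / 2 * tan(3.5 * pi / 180) + 8
  j0 <- max(1L, floor(xbar - halfwin)); j1 <- min(ncol(sub), ceiling(xbar + halfwin))
  xc <- vapply(seq_len(nrow(sub)), function(r) {
    cr <- crossOne(sub[r, j0:j1])
    if (is.na(cr)) NA_real_ else cr + j0 - 1
  }, numeric(1))
  list(xc = xc, rows = seq_len(nrow(sub)), lo = lo, hi = hi, pol = pol)
}

#' Estimate the tilt angle of an edge
#'
#' Locates the mid-level crossing of each row by linear interpolation and
#' fits a least-squares line through the crossings. A warning (not an error)
#' is raised when the angle falls outside the 1.5-3 degree range recommended
#' for presampled MTF measurement.
#'
#' @param image an \linkS4class{ImageFrame} containing a nearly vertical edge.
#' @param roi optional \linkS4class{ROIRect} spanning the edge (default:
#'   whole frame).
#' @return Edge tilt from the column axis, degrees (positive).
#' @export
estimateEdgeAngle <- function(image, roi = NULL) {
  stopifnot(is(image, "ImageFrame"))
  sub <- if (is.null(roi)) image@data else roiSubmatrix(image, roi)
  cr <- edgeCrossings(sub)
  bad <- sum(is.na(cr$xc))
  if (bad > 0.1 * length(cr$xc))
    stop("edge-not-found error: no mid-level crossing in ",
         bad, " of ", length(cr$xc), " rows")
  ok <- !is.na(cr$xc)
  fit <- stats::lm.fit(cbind(1, cr$rows[ok]), cr$xc[ok])
  angle <- atan(abs(fit$coefficients[2L])) * 180 / pi
  if (angle < 1.5 || angle > 3)
    warning(sprintf("edge angle %.2f deg outside the recommended 1.5-3 deg range",
                    angle))
  unname(angle)
}

#' Build the oversampled edge spread function
#'
#' Projects every pixel of the ROI onto the edge-normal axis and bins the
#' values at pitch/oversample; each bin is the mean of its members and empty
#' bins are filled by linear interpolation of their neighbours. The tilt
#' makes consecutive rows sample the edge at staggered sub-pixel phases,
#' which is what removes aliasing from the presampled estimate.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param roi optional \linkS4class{ROIRect} (default: whole frame).
#' @param angle edge tilt, degrees (e.g. from
#'   \code{\link{estimateEdgeAngle}}).
#' @param oversample sub-pixel bins per pixel (>= 4; default 10).
#' @return An \linkS4class{OversampledESF}.
#' @export
buildESF <- function(image, roi = NULL, angle, oversample = 10L) {
  stopifnot(is(image, "ImageFrame"))
  if (oversample < 4) stop("oversample must be >= 4")
  sub <- if (is.null(roi)) image@data else roiSubmatrix(image, roi)
  a <- image@pixelPitch
  cr <- edgeCrossings(sub)
  ok <- !is.na(cr$xc)
  if (sum(!ok) > 0.1 * length(cr$xc))
    stop("edge-not-found error: too many rows without a mid-level crossing")
  th <- angle * pi / 180
  # slope sign from the crossings; the given angle fixes its magnitude
  fit <- stats::lm.fit(cbind(1, cr$rows[ok]), cr$xc[ok])
  b <- abs(tan(th)) * sign(fit$coefficients[2L])
  rbar <- mean(cr$rows[ok])
  x0 <- mean(cr$xc[ok] - b * (cr$rows[ok] - rbar))
  rows <- matrix(seq_len(nrow(sub)), nrow(sub), ncol(sub))
  cols <- matrix(seq_len(ncol(sub)), nrow(sub), ncol(sub), byrow = TRUE)
  d <- (cols - (x0 + b * (rows - rbar))) * cos(th) * a
  bw <- a / oversample
  idx <- floor((d - min(d)) / bw) + 1L
  nb <- max(idx)
  if (nb < 20)
    stop("insufficient-data error: only ", nb, " ESF bins across the record")
  sums <- rowsum(as.vector(sub), as.vector(idx))
  cnts <- tabulate(idx, nbins = nb)
  # trim sparse bins at the record ends (frame corners put only a handful of
  # pixels there, so their means are much noisier than interior bins)
  dense <- which(cnts >= 0.5 * stats::median(cnts[cnts > 0]))
  keep <- min(dense):max(dense)
  pos <- min(d) + (keep - 0.5) * bw
  vals <- rep(NA_real_, length(keep))
  filledAll <- as.integer(rownames(sums))
  inKeep <- filledAll %in% keep
  vals[match(filledAll[inKeep], keep)] <-
    sums[inKeep] / cnts[filledAll[inKeep]]
  if (anyNA(vals)) {
    ok <- which(!is.na(vals))
    vals <- stats::approx(pos[ok], vals[ok], xout = pos, rule = 2)$y
  }
  nb <- length(keep)
  if (nb < 20)
    stop("insufficient-data error: only ", nb, " ESF bins across the record")
  new("OversampledESF", positions = pos, values = vals, binWidth = bw,
      pixelPitch = a)
}

#' Compute the presampled MTF from an oversampled ESF
#'
#' The LSF is the central finite difference of the ESF; a Hann window centred
#' on the LSF peak and spanning the full record suppresses leakage; the
#' discrete Fourier transform magnitude is divided by the central-difference
#' transfer sin(2 pi f d)/(2 pi f d) (d = bin width) and normalized to 1 at
#' f = 0. The curve is reported on a uniform grid up to the detector Nyquist
#' frequency. The result is independent of edge polarity and of any positive
#' scaling of the image.
#'
#' @param esf an \linkS4class{OversampledESF}.
#' @param freqStep reported frequency step, lp/mm (default 0.05).
#' @param window apply the Hann window (default TRUE; switchable for
#'   diagnostics).
#' @return An \linkS4class{MTFCurve}.
#' @export
esfToMTF <- function(esf, freqStep = 0.05, window = TRUE) {
  stopifnot(is(esf, "OversampledESF"))
  v <- esf@values
  delta <- esf@binWidth
  n <- length(v)
  lsf <- (v[3:n] - v[1:(n - 2L)]) / (2 * delta)
  m <- length(lsf)
  if (window) {
    # locate the peak on a pixel-width moving average so single noisy bins
    # cannot steal the window centre from the true transition
    k <- max(3L, as.integer(round(esf@pixelPitch / delta)))
    if (k %% 2L == 0L) k <- k + 1L
    sm <- stats::filter(abs(lsf), rep(1 / k, k), sides = 2)
    sm[is.na(sm)] <- 0
    p <- which.max(sm)
    i <- seq_len(m)
    w <- ifelse(abs(i - p) <= m / 2, 0.5 * (1 + cos(2 * pi * (i - p) / m)), 0)
    lsf <- lsf * w
  }
  M <- 2^ceiling(log2(max(4 * m, 4096)))
  X <- stats::fft(c(lsf, rep(0, M - m)))
  f <- (0:(M - 1)) / (M * delta)
  mag <- Mod(X)
  if (mag[1L] <= .Machine$double.eps * sum(abs(lsf)) || mag[1L] == 0)
    stop("normalization error: zero total LSF area")
  mtf <- mag / abs(sinc(2 * pi * f * delta))
  mtf <- mtf / mtf[1L]
  nyq <- 1 / (2 * esf@pixelPitch)
  grid <- seq(0, nyq, by = freqStep)
  vals <- stats::approx(f[seq_len(M %/% 2)], mtf[seq_len(M %/% 2)],
                        xout = grid)$y
  vals[1L] <- 1
  new("MTFCurve", frequencies = grid, values = vals, nyquist = nyq)
}

#' Measure the presampled MTF of a tilted-edge image
#'
#' Convenience wrapper: estimate the edge angle, build the oversampled ESF
#' and transform to the MTF.
#'
#' @inheritParams buildESF
#' @inheritParams esfToMTF
#' @return An \linkS4class{MTFCurve}.
#' @export
measureMTF <- function(image, roi = NULL, oversample = 10L, freqStep = 0.05) {
  angle <- estimateEdgeAngle(image, roi)
  esf <- buildESF(image, roi, angle, oversample)
  esfToMTF(esf, freqStep)
}

#' Frequency at which a curve falls to half its zero-frequency value
#'
#' @param curve a \linkS4class{FrequencyCurve} (typically an MTF).
#' @return The 50% frequency, lp/mm (NA when the curve never falls below
#'   half).
#' @export
mtf50 <- function(curve) {
  f <- curve@frequencies; v <- curve@values / curve@values[1L]
  below <- which(v <= 0.5)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(f[1L])
  f[i - 1L] + (0.5 - v[i - 1L]) * (f[i] - f[i - 1L]) / (v[i] - v[i - 1L])
}
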