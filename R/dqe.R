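# Detective quantum efficiency: combine the presampled MTF, the NNPS and the
# input photon statistics of the beam. DQE(f) = MTF^2(f) / (Phi * NNPS(f))
# with Phi = kerma x SNR^2-per-kerma; NNPS enters to the first power, which
# is the dimensionally consistent form (NNPS in mm^2, Phi in mm^-2).

#' Compute the DQE from measured MTF and NNPS
#'
#' The two curves are resampled by linear interpolation onto the coarser of
#' the two frequency grids, restricted to their common frequency range
#' (extrapolation is refused). DQE values are reported without clipping; a
#' warning is emitted if sampling noise pushes a bin above 1.
#'
#' @param mtf an \linkS4class{MTFCurve}.
#' @param nnps an \linkS4class{NNPSCurve}.
#' @param bq a \linkS4class{BeamQuality} (supplies the photon fluence per air
#'   kerma ratio).
#' @param kerma air kerma of the flat-field series, uGy (> 0).
#' @return A \linkS4class{DQECurve}.
#' @export
computeDQE <- function(mtf, nnps, bq, kerma) {
  stopifnot(is(mtf, "MTFCurve"), is(nnps, "NNPSCurve"),
            is(bq, "BeamQuality"))
  if (!is.numeric(kerma) || length(kerma) != 1L || !is.finite(kerma) ||
      kerma <= 0)
    stop("domain error: kerma must be a single positive number (uGy)")
  fLo <- max(min(mtf@frequencies), min(nnps@frequencies))
  fHi <- min(max(mtf@frequencies), max(nnps@frequencies))
  if (fLo >= fHi)
    stop("MTF and NNPS frequency ranges do not overlap")
  stepM <- stats::median(diff(mtf@frequencies))
  stepN <- stats::median(diff(nnps@frequencies))
  coarse <- if (stepM >= stepN) mtf@frequencies else nnps@frequencies
  grid <- coarse[coarse >= fLo - 1e-12 & coarse <= fHi + 1e-12]
  mtfv <- stats::approx(mtf@frequencies, mtf@values, xout = grid)$y
  nnpsv <- stats::approx(nnps@frequencies, nnps@values, xout = grid)$y
  if (any(nnpsv == 0)) {
    f0 <- grid[which(nnpsv == 0)[1L]]
    stop("division error: NNPS is zero at f = ", signif(f0, 4), " lp/mm")
  }
  phi <- fluenceFromKerma(bq, kerma)
  dqe <- mtfv^2 / (phi * nnpsv)
  if (any(dqe > 1))
    warning("DQE exceeds 1 in ", sum(dqe > 1),
            " bins (sampling noise); values reported unclipped")
  new("DQECurve", frequencies = grid, values = dqe, kerma = kerma,
      beam = bq@name)
}
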