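# Frame and curve I/O. Pixel pitch is required metadata at read time (the
# frequency axes depend on it): it is taken from an explicit argument or
# from the YAML sidecar written next to each frame, never inferred.

rawDtypes <- list(
  uint16 = list(size = 2L, what = "integer", signed = FALSE),
  float32 = list(size = 4L, what = "double"),
  float64 = list(size = 8L, what = "double")
)

sidecarPath <- function(path) paste0(path, ".yaml")

#' Write a frame to disk
#'
#' TIFF frames are written as 16-bit little-endian single-page grayscale
#' (values must already be integers in [0, 65535]; they are stored exactly,
#' no rescale). Raw frames are written row-major in the requested dtype. A
#' YAML sidecar (\code{<path>.yaml}) records the pixel pitch and, for raw
#' files, the geometry.
#'
#' @param image an \linkS4class{ImageFrame}.
#' @param path output path.
#' @param format \code{"tiff"} or \code{"raw"}.
#' @param dtype raw sample type: \code{"uint16"}, \code{"float32"} or
#'   \code{"float64"}.
#' @param endianness raw byte order, \code{"little"} or \code{"big"}.
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(image, path, format = c("tiff", "raw"),
                       dtype = "float64", endianness = "little") {
  stopifnot(is(image, "ImageFrame"))
  format <- match.arg(format)
  dat <- image@data
  side <- list(pixel_pitch_mm = image@pixelPitch, format = format)
  if (format == "tiff") {
    vals <- round(dat)
    if (any(vals < 0) || any(vals > 65535))
      stop("format error: 16-bit TIFF requires values in [0, 65535]; ",
           "use format = 'raw' with a float dtype for unbounded signal")
    tiff::writeTIFF(vals / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else {
    dt <- rawDtypes[[dtype]]
    if (is.null(dt)) stop("unknown raw dtype '", dtype, "'")
    v <- as.vector(t(dat))                      # row-major
    if (dtype == "uint16") {
      if (any(round(v) < 0) || any(round(v) > 65535))
        stop("format error: uint16 requires values in [0, 65535]")
      v <- as.integer(round(v))
    }
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(v, con, size = dt$size, endian = endianness)
    side <- c(side, list(width = ncol(dat), height = nrow(dat),
                         dtype = dtype, endianness = endianness))
  }
  yaml::write_yaml(side, sidecarPath(path))
  invisible(path)
}

#' Read a frame from disk
#'
#' @param path file path.
#' @param format \code{"tiff"} or \code{"raw"}; defaults to the sidecar's
#'   record, else \code{"tiff"}.
#' @param pitch pixel pitch, mm; defaults to the sidecar's record. Required
#'   one way or the other.
#' @param width,height raw geometry, pixels (required for raw files without
#'   a sidecar).
#' @param dtype,endianness raw sample type and byte order.
#' @return An \linkS4class{ImageFrame}.
#' @export
readFrame <- function(path, format = NULL, pitch = NULL, width = NULL,
                      height = NULL, dtype = NULL, endianness = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  side <- if (file.exists(sidecarPath(path)))
    yaml::read_yaml(sidecarPath(path)) else list()
  format <- format %||% side$format %||% "tiff"
  pitch <- pitch %||% side$pixel_pitch_mm
  if (is.null(pitch))
    stop("pixel pitch is required metadata: pass 'pitch' or provide a ",
         "sidecar ", sidecarPath(path))
  if (format == "tiff") {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    return(imageFrame(matrix(as.numeric(img), nrow(img)), pitch))
  }
  width <- width %||% side$width
  height <- height %||% side$height
  dtype <- dtype %||% side$dtype
  endianness <- endianness %||% side$endianness %||% "little"
  if (is.null(width) || is.null(height) || is.null(dtype))
    stop("raw format requires explicit geometry (width, height, dtype)")
  dt <- rawDtypes[[dtype]]
  if (is.null(dt)) stop("unknown raw dtype '", dtype, "'")
  expect <- as.numeric(width) * as.numeric(height) * dt$size
  actual <- file.size(path)
  if (expect != actual)
    stop("format error: ", path, " holds ", actual, " bytes but ", width,
         " x ", height, " ", dtype, " needs ", expect, " bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = dt$what, n = width * height, size = dt$size,
               signed = if (dtype == "uint16") FALSE else TRUE,
               endian = endianness)
  imageFrame(matrix(as.numeric(v), nrow = height, byrow = TRUE), pitch)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

curveMetric <- function(curve) {
  if (is(curve, "MTFCurve")) "mtf"
  else if (is(curve, "NNPSCurve")) "nnps_mm2"
  else if (is(curve, "DQECurve")) "dqe"
  else "value"
}

#' Write a frequency curve to CSV
#'
#' One header row (\code{frequency_lp_per_mm,<metric>}), values at 9
#' significant digits, preceded by \code{#} comment lines carrying the
#' class-specific metadata so the curve round-trips losslessly.
#'
#' @param curve a \linkS4class{FrequencyCurve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCurve <- function(curve, path) {
  stopifnot(is(curve, "FrequencyCurve"))
  metric <- curveMetric(curve)
  meta <- c(paste0("# class: ", class(curve)))
  if (is(curve, "MTFCurve"))
    meta <- c(meta, sprintf("# nyquist_lp_per_mm: %.9g", curve@nyquist))
  if (is(curve, "NNPSCurve"))
    meta <- c(meta, sprintf("# n_rois: %d", curve@nRois))
  if (is(curve, "DQECurve"))
    meta <- c(meta, sprintf("# kerma_uGy: %.9g", curve@kerma),
              paste0("# beam: ", curve@beam))
  lines <- c(meta,
             paste0("frequency_lp_per_mm,", metric),
             sprintf("%.9g,%.9g", curve@frequencies, curve@values))
  writeLines(lines, path)
  invisible(path)
}

#' Read a frequency curve from CSV
#'
#' @param path CSV path written by \code{\link{writeCurve}} (or any CSV with
#'   a \code{frequency_lp_per_mm} column plus one value column).
#' @return The reconstructed \linkS4class{FrequencyCurve} subclass.
#' @export
readCurve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path)
  meta <- grep("^#", raw, value = TRUE)
  metaVal <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, ": "), "", hit[1L]) else NULL
  }
  df <- utils::read.csv(text = raw[!grepl("^#", raw)])
  if (!"frequency_lp_per_mm" %in% names(df))
    stop("format error: missing 'frequency_lp_per_mm' column in ", path)
  metric <- setdiff(names(df), "frequency_lp_per_mm")[1L]
  f <- df$frequency_lp_per_mm
  v <- df[[metric]]
  cls <- metaVal("class") %||% switch(metric, mtf = "MTFCurve",
                                      nnps_mm2 = "NNPSCurve",
                                      dqe = "DQECurve", "FrequencyCurve")
  switch(cls,
    MTFCurve = new("MTFCurve", frequencies = f, values = v,
                   nyquist = as.numeric(metaVal("nyquist_lp_per_mm") %||%
                                          max(f))),
    NNPSCurve = new("NNPSCurve", frequencies = f, values = v,
                    nRois = as.integer(metaVal("n_rois") %||% 0L)),
    DQECurve = new("DQECurve", frequencies = f, values = v,
                   kerma = as.numeric(metaVal("kerma_uGy") %||% 1),
                   beam = metaVal("beam") %||% "unknown"),
    new("FrequencyCurve", frequencies = f, values = v))
}
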