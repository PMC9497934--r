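# Registries of fixed protocol constants: detector specifications and
# standardized RQA beam qualities, plus the air kerma -> photon fluence
# conversion that links dose to input quantum statistics.

# fold names for lookup: trim, case-fold, drop internal whitespace/hyphens,
# so "rqa-5", "RQA 5" and "RQA5" are the same key
normalizeKey <- function(name) {
  toupper(gsub("[[:space:]-]+", "", trimws(name)))
}

registryEnv <- new.env(parent = emptyenv())

loadRegistry <- function(which, config = NULL) {
  path <- if (is.null(config))
    system.file("extdata", which, package = "panelIQ", mustWork = TRUE)
  else config
  key <- paste0(which, "::", path)
  if (is.null(registryEnv[[key]]))
    registryEnv[[key]] <- yaml::read_yaml(path)
  registryEnv[[key]]
}

#' Look up a standardized beam quality
#'
#' Returns the registered constants of an RQA beam quality: tube voltage,
#' added aluminium filtration, half-value layer and squared SNR per air kerma
#' (equivalently, photon fluence per mm^2 per uGy). Lookups are
#' case-insensitive and ignore whitespace and hyphens, so \code{"rqa-5"}
#' resolves to \code{"RQA5"}.
#'
#' @param name beam quality name, one of \code{"RQA3"}, \code{"RQA5"}.
#' @param protocol protocol revision of the constants: \code{"2015"}
#'   (default, the current standard) or \code{"2003"} (superseded alternates,
#'   retained for comparison with older measurements).
#' @param config optional path to a user YAML file overriding the packaged
#'   registry (same schema).
#' @return A \linkS4class{BeamQuality}.
#' @examples
#' beamQuality("RQA5")
#' beamQuality("rqa-3")
#' @export
beamQuality <- function(name, protocol = c("2015", "2003"), config = NULL) {
  protocol <- match.arg(protocol)
  reg <- loadRegistry("beam_qualities.yaml", config)[[protocol]]
  keys <- vapply(names(reg), normalizeKey, character(1))
  hit <- match(normalizeKey(name), keys)
  if (is.na(hit))
    stop("unknown beam quality '", name, "'; registered beam qualities: ",
         paste(names(reg), collapse = ", "))
  rec <- reg[[hit]]
  new("BeamQuality",
      name = names(reg)[hit],
      tubeVoltage = as.numeric(rec$tube_voltage),
      addedFiltration = as.numeric(rec$added_filtration),
      halfValueLayer = as.numeric(rec$half_value_layer),
      snr2PerKerma = as.numeric(rec$snr2_per_kerma),
      protocol = protocol)
}

#' List registered beam quality names
#' @inheritParams beamQuality
#' @return Character vector of names.
#' @export
listBeamQualities <- function(protocol = c("2015", "2003"), config = NULL) {
  protocol <- match.arg(protocol)
  names(loadRegistry("beam_qualities.yaml", config)[[protocol]])
}

#' Look up a detector specification
#'
#' Returns the physical specification of one of the registered CsI(Tl)
#' flat-panel detectors. Lookups are case-insensitive and ignore whitespace
#' and hyphens.
#'
#' @param name detector model, one of \code{"FXRD-4343VAW"},
#'   \code{"FXRD-4343VAW Plus"}, \code{"FXRD-4343FAW"}.
#' @param config optional path to a user YAML registry.
#' @return A \linkS4class{DetectorSpec}.
#' @examples
#' detectorSpec("FXRD-4343FAW")
#' @export
detectorSpec <- function(name, config = NULL) {
  reg <- loadRegistry("detectors.yaml", config)
  keys <- vapply(names(reg), normalizeKey, character(1))
  hit <- match(normalizeKey(name), keys)
  if (is.na(hit))
    stop("unknown detector '", name, "'; registered detectors: ",
         paste(names(reg), collapse = ", "))
  rec <- reg[[hit]]
  new("DetectorSpec",
      name = names(reg)[hit],
      scintillatorThicknessFactor = as.numeric(rec$scintillator_thickness_factor),
      pixelPitch = as.numeric(rec$pixel_pitch),
      matrix = as.integer(rec$matrix),
      detectionArea = as.integer(rec$detection_area),
      weight = as.numeric(rec$weight))
}

#' List registered detector names
#' @inheritParams detectorSpec
#' @return Character vector of names.
#' @export
listDetectorSpecs <- function(config = NULL) {
  names(loadRegistry("detectors.yaml", config))
}

#' Convert air kerma to photon fluence
#'
#' The input photon fluence of a standardized beam is the air kerma times the
#' beam's squared SNR per air kerma (which is what makes that constant the
#' "photon fluence per air kerma ratio"). Linear in kerma.
#'
#' @param bq a \linkS4class{BeamQuality}.
#' @param kerma air kerma, uGy; must be >= 0.
#' @return Photon fluence, photons/mm^2.
#' @examples
#' fluenceFromKerma(beamQuality("RQA5"), 2.5)
#' @export
fluenceFromKerma <- function(bq, kerma) {
  stopifnot(is(bq, "BeamQuality"))
  if (!is.numeric(kerma) || any(!is.finite(kerma)) || any(kerma < 0))
    stop("kerma must be finite and >= 0 (uGy)")
  kerma * bq@snr2PerKerma
}
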