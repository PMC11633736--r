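#' @import methods
NULL

#' BandSpectrum: vibrational band model for one chemical species
#'
#' Holds separate IR and Raman band lists for a species, reflecting the
#' complementary selection rules of infrared absorption (dipole-moment
#' derivative) and Raman scattering (polarizability derivative). Each band is
#' a line profile with a center (cm^-1), full width at half maximum (cm^-1)
#' and a dimensionless relative amplitude. The two cross-section scale
#' factors carry the (relative) IR versus Raman cross-section disparity; they
#' multiply the evaluated spectra of the respective modality.
#'
#' @slot species character(1), species identifier.
#' @slot bands data.frame with columns \code{center}, \code{fwhm},
#'   \code{amplitude} and \code{modality} (\code{"IR"} or \code{"Raman"}).
#' @slot irScale numeric(1), relative IR cross-section scale.
#' @slot ramanScale numeric(1), relative Raman cross-section scale.
#' @slot lineShape character(1), \code{"lorentzian"} (default) or
#'   \code{"gaussian"}.
#'
#' @seealso [bandSpectrum()], [speciesPreset()], [evaluateSpectrum()]
#' @exportClass BandSpectrum
setClass("BandSpectrum",
    representation(
        species   = "character",
        bands     = "data.frame",
        irScale   = "numeric",
        ramanScale = "numeric",
        lineShape = "character"
    ),
    prototype(
        species = NA_character_,
        bands = data.frame(center = numeric(), fwhm = numeric(),
                           amplitude = numeric(), modality = character()),
        irScale = 1, ramanScale = 1, lineShape = "lorentzian"
    )
)

setValidity("BandSpectrum", function(object) {
    b <- object@bands
    msg <- character()
    need <- c("center", "fwhm", "amplitude", "modality")
    if (!all(need %in% names(b)))
        return(paste("bands must have columns:", paste(need, collapse = ", ")))
    if (nrow(b)) {
        if (any(b$center <= 0)) msg <- c(msg, "band centers must be > 0")
        if (any(b$fwhm <= 0))   msg <- c(msg, "band fwhm must be > 0")
        if (any(b$amplitude < 0)) msg <- c(msg, "band amplitudes must be >= 0")
        if (!all(b$modality %in% c("IR", "Raman")))
            msg <- c(msg, "band modality must be 'IR' or 'Raman'")
    }
    if (length(object@species) != 1L) msg <- c(msg, "species must be length 1")
    if (object@irScale < 0 || object@ramanScale < 0)
        msg <- c(msg, "cross-section scales must be >= 0")
    if (!object@lineShape %in% c("lorentzian", "gaussian"))
        msg <- c(msg, "lineShape must be 'lorentzian' or 'gaussian'")
    if (length(msg)) msg else TRUE
})

#' ConcentrationMap: per-species spatial concentration grid
#'
#' A stack of non-negative 2-D concentration grids, one per species, sharing
#' a physical pixel size. The origin convention is pixel-centered with index
#' (1,1) at the top-left; the first array dimension is y (rows), the second
#' x (columns), the third species.
#'
#' Droplet-field phantoms additionally carry a ground-truth table
#' (one row per rendered object) in the \code{groundTruth} slot.
#'
#' @slot species character vector of species names (third array dimension).
#' @slot grid numeric array \code{[y, x, species]}, all values >= 0.
#' @slot pixelSize numeric(1), pixel size in micrometers.
#' @slot groundTruth data.frame, per-object ground truth (may be empty).
#'
#' @seealso [makeBeadMap()], [makeMixtureMap()], [makeDropletField()]
#' @exportClass ConcentrationMap
setClass("ConcentrationMap",
    representation(
        species = "character",
        grid = "array",
        pixelSize = "numeric",
        groundTruth = "data.frame"
    ),
    prototype(groundTruth = data.frame())
)

setValidity("ConcentrationMap", function(object) {
    msg <- character()
    d <- dim(object@grid)
    if (length(d) != 3L)
        return("grid must be a 3-D array [y, x, species]")
    if (d[3] != length(object@species))
        msg <- c(msg, "third grid dimension must match length(species)")
    if (any(object@grid < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive value (um)")
    if (length(msg)) msg else TRUE
})

#' ContrastPair: focal modulation-depth maps for the two channels
#'
#' Per-pixel physical contrast produced by the optical forward model: the
#' per-pulse stimulated-Raman-loss fractional probe loss (\code{deltaSrl})
#' and the photothermal fractional transmission modulation at the configured
#' average mid-IR power (\code{deltaPt}). Both are dimensionless, >= 0, and
#' assumed small (a warning is raised above 0.2, the small-signal regime
#' bound).
#'
#' @slot deltaSrl numeric matrix, per-pulse SRL fractional loss.
#' @slot deltaPt numeric matrix, photothermal transmission-modulation depth.
#' @slot pixelSize numeric(1), micrometers.
#' @slot meta list of excitation/gain provenance.
#'
#' @seealso [renderContrast()]
#' @exportClass ContrastPair
setClass("ContrastPair",
    representation(deltaSrl = "matrix", deltaPt = "matrix",
                   pixelSize = "numeric", meta = "list"),
    prototype(meta = list())
)

setValidity("ContrastPair", function(object) {
    msg <- character()
    if (!identical(dim(object@deltaSrl), dim(object@deltaPt)))
        msg <- c(msg, "deltaSrl and deltaPt must share dimensions")
    if (any(object@deltaSrl < 0) || any(object@deltaPt < 0))
        msg <- c(msg, "contrast values must be >= 0")
    if (length(msg)) msg else TRUE
})

#' TimeTrace: sampled probe-intensity waveform for one pixel dwell
#'
#' The probe-intensity waveform seen by the detector during one pixel dwell:
#' an 80-MHz train of pulse-energy impulses (one sample period wide), with
#' Raman-loss gating and the photothermal envelope applied, plus optional
#' detector noise. Intensities are in arbitrary units and non-negative.
#' The \code{meta} slot records full configuration provenance (pulse-train,
#' thermal and noise configurations plus seed) so a trace can be regenerated
#' bit-identically.
#'
#' @slot samples numeric vector of intensity samples (>= 0).
#' @slot sampleRate numeric(1), samples per second.
#' @slot meta list of configuration provenance.
#'
#' @seealso [synthTrace()], [lockin()], [powerSpectrum()]
#' @exportClass TimeTrace
setClass("TimeTrace",
    representation(samples = "numeric", sampleRate = "numeric", meta = "list"),
    prototype(meta = list())
)

setValidity("TimeTrace", function(object) {
    msg <- character()
    if (length(object@samples) < 1L) msg <- c(msg, "trace must be non-empty")
    if (any(object@samples < 0)) msg <- c(msg, "samples must be >= 0")
    if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
        msg <- c(msg, "sampleRate must be a single positive value")
    if (length(msg)) msg else TRUE
})

#' ImagePair: co-registered IR and Raman channel images
#'
#' The two demodulated channel images assembled by a virtual scan. Both
#' derive from one waveform per pixel (the simultaneity guarantee of
#' single-probe detection), so they are exactly co-registered by
#' construction.
#'
#' @slot ir numeric matrix, 100-kHz (photothermal) channel image.
#' @slot raman numeric matrix, 20-MHz (SRL) channel image.
#' @slot pixelSize numeric(1), micrometers.
#' @slot meta list: excitation wavenumbers, powers, gains, scan provenance.
#'
#' @seealso [scanImage()]
#' @exportClass ImagePair
setClass("ImagePair",
    representation(ir = "matrix", raman = "matrix",
                   pixelSize = "numeric", meta = "list"),
    prototype(meta = list())
)

setValidity("ImagePair", function(object) {
    if (!identical(dim(object@ir), dim(object@raman)))
        return("ir and raman images must share dimensions")
    TRUE
})

#' SpectrumResult: quasi-simultaneous IR and Raman point spectra
#'
#' Result of a two-pass excitation-wavelength sweep at a fixed pixel: first
#' the IR wavenumber is swept (2 cm^-1 grid, emulating fast tuning of a
#' quantum cascade laser), then the Raman detuning (8 cm^-1 grid). Values
#' are magnitude-demodulated channel amplitudes, hence non-negative.
#'
#' @slot irAxis,irValues numeric vectors, IR sweep axis (cm^-1) and values.
#' @slot ramanAxis,ramanValues numeric vectors, Raman sweep axis and values.
#' @slot meta list of sweep provenance.
#'
#' @seealso [sweepSpectrum()]
#' @exportClass SpectrumResult
setClass("SpectrumResult",
    representation(irAxis = "numeric", irValues = "numeric",
                   ramanAxis = "numeric", ramanValues = "numeric",
                   meta = "list"),
    prototype(meta = list())
)

setValidity("SpectrumResult", function(object) {
    msg <- character()
    if (length(object@irAxis) != length(object@irValues))
        msg <- c(msg, "irAxis and irValues lengths differ")
    if (length(object@ramanAxis) != length(object@ramanValues))
        msg <- c(msg, "ramanAxis and ramanValues lengths differ")
    if (length(object@irAxis) > 1 && any(diff(object@irAxis) <= 0))
        msg <- c(msg, "irAxis must be strictly increasing")
    if (length(object@ramanAxis) > 1 && any(diff(object@ramanAxis) <= 0))
        msg <- c(msg, "ramanAxis must be strictly increasing")
    if (length(msg)) msg else TRUE
})
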