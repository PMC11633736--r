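#' Accessor generics
#'
#' Accessors for the core classes: \code{pixelSize} (micrometers),
#' \code{speciesNames}, \code{concGrid} (the \code{[y, x, species]} array),
#' \code{groundTruth} (phantom ground-truth table), \code{samples} and
#' \code{sampleRate} (waveform), \code{irImage}/\code{ramanImage} (channel
#' images), \code{deltaSrl}/\code{deltaPt} (contrast maps), and
#' \code{traceMeta} (configuration provenance).
#'
#' @param x an object of the corresponding class.
#' @return The slot value; see the class documentation for units.
#' @name accessors
#' @aliases pixelSize speciesNames concGrid groundTruth samples sampleRate
#'   irImage ramanImage deltaSrl deltaPt traceMeta
NULL

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname accessors
#' @export
setGeneric("concGrid", function(x) standardGeneric("concGrid"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("irImage", function(x) standardGeneric("irImage"))

#' @rdname accessors
#' @export
setGeneric("ramanImage", function(x) standardGeneric("ramanImage"))

#' @rdname accessors
#' @export
setGeneric("deltaSrl", function(x) standardGeneric("deltaSrl"))

#' @rdname accessors
#' @export
setGeneric("deltaPt", function(x) standardGeneric("deltaPt"))

#' @rdname accessors
#' @export
setGeneric("traceMeta", function(x) standardGeneric("traceMeta"))

#' Evaluate a band spectrum on a wavenumber axis
#'
#' @param spectrum a [BandSpectrum-class].
#' @param wavenumbers strictly increasing numeric axis (cm^-1).
#' @param modality \code{"IR"} or \code{"Raman"}.
#' @param ... further arguments for methods.
#' @return numeric vector of non-negative intensities, same length as
#'   \code{wavenumbers}.
#' @export
setGeneric("evaluateSpectrum",
    function(spectrum, wavenumbers, modality, ...)
        standardGeneric("evaluateSpectrum"))
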