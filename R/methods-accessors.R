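#' @rdname accessors
#' @export
setMethod("pixelSize", "ConcentrationMap", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ContrastPair", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImagePair", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("speciesNames", "ConcentrationMap", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesNames", "BandSpectrum", function(x) x@species)

#' @rdname accessors
#' @export
setMethod("concGrid", "ConcentrationMap", function(x) x@grid)

#' @rdname accessors
#' @export
setMethod("groundTruth", "ConcentrationMap", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setMethod("samples", "TimeTrace", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("sampleRate", "TimeTrace", function(x) x@sampleRate)

#' @rdname accessors
#' @export
setMethod("traceMeta", "TimeTrace", function(x) x@meta)

#' @rdname accessors
#' @export
setMethod("irImage", "ImagePair", function(x) x@ir)

#' @rdname accessors
#' @export
setMethod("ramanImage", "ImagePair", function(x) x@raman)

#' @rdname accessors
#' @export
setMethod("deltaSrl", "ContrastPair", function(x) x@deltaSrl)

#' @rdname accessors
#' @export
setMethod("deltaPt", "ContrastPair", function(x) x@deltaPt)

setMethod("show", "BandSpectrum", function(object) {
    b <- object@bands
    cat("BandSpectrum for", object@species, "\n",
        " ", sum(b$modality == "IR"), "IR band(s),",
        sum(b$modality == "Raman"), "Raman band(s);",
        "line shape:", object@lineShape, "\n",
        "  scales: IR", object@irScale, "/ Raman", object@ramanScale, "\n")
    if (nrow(b)) {
        o <- b[order(b$modality, b$center), ]
        cat(sprintf("  %-6s %8s %6s %6s\n", "mod", "center", "fwhm", "amp"))
        for (i in seq_len(nrow(o)))
            cat(sprintf("  %-6s %8.0f %6.1f %6.2f\n", o$modality[i],
                        o$center[i], o$fwhm[i], o$amplitude[i]))
    }
    invisible(NULL)
})

setMethod("show", "ConcentrationMap", function(object) {
    d <- dim(object@grid)
    cat("ConcentrationMap:", d[1], "x", d[2], "pixels,",
        d[3], "species (", paste(object@species, collapse = ", "), ")\n",
        " pixel size:", object@pixelSize, "um; field:",
        round(d[2] * object@pixelSize, 3), "x",
        round(d[1] * object@pixelSize, 3), "um\n")
    if (nrow(object@groundTruth))
        cat("  ground truth:", nrow(object@groundTruth), "objects\n")
    invisible(NULL)
})

setMethod("show", "ContrastPair", function(object) {
    cat("ContrastPair:", paste(dim(object@deltaSrl), collapse = " x "),
        "pixels @", object@pixelSize, "um\n",
        sprintf("  delta_srl: max %.3g   delta_pt: max %.3g\n",
                max(object@deltaSrl), max(object@deltaPt)))
    invisible(NULL)
})

setMethod("show", "TimeTrace", function(object) {
    n <- length(object@samples)
    cat(sprintf(
        "TimeTrace: %d samples @ %.4g GS/s (%.3g us dwell), mean %.4g\n",
        n, object@sampleRate / 1e9, n / object@sampleRate * 1e6,
        mean(object@samples)))
    invisible(NULL)
})

setMethod("show", "ImagePair", function(object) {
    cat("ImagePair:", paste(dim(object@ir), collapse = " x "),
        "pixels @", object@pixelSize, "um\n",
        sprintf("  IR channel:    max %.4g\n  Raman channel: max %.4g\n",
                max(object@ir), max(object@raman)))
    invisible(NULL)
})

setMethod("show", "SpectrumResult", function(object) {
    cat("SpectrumResult:\n",
        sprintf("  IR sweep:    %d points, %.0f-%.0f cm^-1\n",
                length(object@irAxis), min(object@irAxis), max(object@irAxis)),
        sprintf("  Raman sweep: %d points, %.0f-%.0f cm^-1\n",
                length(object@ramanAxis), min(object@ramanAxis),
                max(object@ramanAxis)))
    invisible(NULL)
})
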