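#' Construct a vibrational band table row
#'
#' @param center band center (cm^-1), > 0.
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param amplitude relative strength, >= 0.
#' @param modality \code{"IR"} or \code{"Raman"}.
#' @return one-row data.frame suitable for [bandSpectrum()].
#' @export
band <- function(center, fwhm, amplitude = 1, modality = c("IR", "Raman")) {
    modality <- match.arg(modality)
    assertScalar(center, "center"); assertScalar(fwhm, "fwhm")
    assertScalar(amplitude, "amplitude", strict = FALSE)
    data.frame(center = center, fwhm = fwhm, amplitude = amplitude,
               modality = modality, stringsAsFactors = FALSE)
}

#' Construct a BandSpectrum
#'
#' @param species species identifier.
#' @param bands data.frame of bands, e.g. built by \code{rbind()}-ing
#'   [band()] rows.
#' @param irScale,ramanScale relative cross-section scales multiplying the
#'   evaluated IR and Raman spectra. Infrared absorption cross sections
#'   exceed Raman cross sections by many orders of magnitude; because the
#'   instrument gains absorb most of that disparity, the defaults keep both
#'   scales at 1 and leave the ratio configurable.
#' @param lineShape \code{"lorentzian"} (conventional for vibrational bands)
#'   or \code{"gaussian"}.
#' @return a [BandSpectrum-class].
#' @examples
#' pmma <- speciesPreset("pmma")
#' nu <- seq(915, 2335, by = 2)
#' ir <- evaluateSpectrum(pmma, nu, "IR")
#' nu[which.max(ir)]  # 1730, the C=O stretching band
#' @export
bandSpectrum <- function(species, bands, irScale = 1, ramanScale = 1,
                         lineShape = c("lorentzian", "gaussian")) {
    new("BandSpectrum", species = as.character(species), bands = bands,
        irScale = irScale, ramanScale = ramanScale,
        lineShape = match.arg(lineShape))
}

# Preset band tables. Band positions are the assignments used throughout
# this instrument class (PMMA C=O 1730 / CH3 2957; lipid C=O 1750 and CH2
# 2850; amide I 1655 and amide II 1545; proteoglycan 1080; phospholipid
# 1069 / 1224; cholesterol-methyl 1375 / 1465 / 2870; DiPhDY alkyne 2216 and
# ring 1593; TPP 1477). Relative amplitudes and widths are configuration
# choices, not literature values.
.presets <- list(
    pmma = list(
        ir = list(c(1730, 22, 1.0)),
        raman = list(c(2957, 34, 1.0), c(2850, 30, 0.45), c(1459, 18, 0.17))),
    oil = list(
        ir = list(c(1750, 24, 1.0)),
        raman = list(c(2850, 32, 1.0))),
    palmitic_acid = list(
        ir = list(c(1700, 20, 1.0), c(1470, 18, 0.45)),
        raman = list(c(2850, 32, 1.0))),
    diphdy = list(
        ir = list(),
        raman = list(c(2216, 14, 1.0), c(1593, 12, 0.8))),
    tpp = list(
        ir = list(c(1477, 14, 1.0)),
        raman = list(c(1587, 14, 0.5))),
    lipid = list(
        ir = list(c(1750, 24, 1.0), c(1465, 18, 0.5)),
        raman = list(c(2850, 32, 1.0), c(2870, 30, 0.4))),
    protein = list(
        ir = list(c(1655, 30, 1.0), c(1545, 28, 0.6)),
        raman = list(c(2930, 36, 1.0))),
    proteoglycan = list(
        ir = list(c(1080, 26, 1.0)),
        raman = list(c(2930, 36, 0.3))),
    phospholipid = list(
        ir = list(c(1069, 22, 0.8), c(1224, 24, 0.7)),
        raman = list(c(2850, 32, 0.8))),
    cholesterol = list(
        ir = list(c(1375, 16, 0.7), c(1465, 18, 0.9)),
        raman = list(c(2870, 28, 1.0)))
)

#' Species band-spectrum presets
#'
#' Returns a ready-made [BandSpectrum-class] for one of the built-in
#' species. Available presets:
#' \code{"pmma"}, \code{"oil"}, \code{"palmitic_acid"}, \code{"diphdy"}
#' (1,4-diphenylbutadiyne), \code{"tpp"} (triphenyl phosphine),
#' \code{"lipid"}, \code{"protein"}, \code{"proteoglycan"},
#' \code{"phospholipid"}, \code{"cholesterol"}.
#'
#' Note the IR/Raman exclusivity built into the chemical-mixture presets:
#' palmitic acid carries the IR 1700 cm^-1 carbonyl band, DiPhDY the Raman
#' 2216 and 1593 cm^-1 bands, and TPP the IR 1477 cm^-1 band. This mapping
#' is a configuration choice of the presets (editable via [bandSpectrum()]),
#' not a claim about ground truth.
#'
#' @param name preset name (see above).
#' @param ... passed to [bandSpectrum()] (e.g. \code{lineShape}).
#' @return a [BandSpectrum-class].
#' @export
speciesPreset <- function(name, ...) {
    name <- match.arg(name, names(.presets))
    p <- .presets[[name]]
    rows <- c(
        lapply(p$ir, function(v) band(v[1], v[2], v[3], "IR")),
        lapply(p$raman, function(v) band(v[1], v[2], v[3], "Raman")))
    bands <- if (length(rows)) do.call(rbind, rows) else band(1, 1, 0)[0, ]
    bandSpectrum(name, bands, ...)
}

#' Build a named list of preset spectra
#'
#' @param names character vector of preset names.
#' @return named list of [BandSpectrum-class] objects, usable as the
#'   spectral library of [renderContrast()] and [scanImage()].
#' @export
presetLibrary <- function(names) {
    out <- lapply(names, speciesPreset)
    names(out) <- names
    out
}

#' @describeIn evaluateSpectrum Sum of line profiles over the bands of the
#'   requested modality, multiplied by that modality's cross-section scale.
#'   Lorentzian profile: \eqn{a (w/2)^2 / ((\nu - c)^2 + (w/2)^2)} (unit
#'   amplitude at the center, half maximum at half width); Gaussian profile
#'   has matching FWHM.
#' @export
setMethod("evaluateSpectrum", "BandSpectrum",
    function(spectrum, wavenumbers, modality, ...) {
    if (length(modality) != 1L || !modality %in% c("IR", "Raman"))
        stop("unknown modality: must be 'IR' or 'Raman'")
    if (!is.numeric(wavenumbers) || length(wavenumbers) < 1L)
        stop("'wavenumbers' must be a numeric vector")
    if (length(wavenumbers) > 1L && any(diff(wavenumbers) <= 0))
        stop("'wavenumbers' must be strictly increasing")
    b <- spectrum@bands[spectrum@bands$modality == modality, , drop = FALSE]
    out <- numeric(length(wavenumbers))
    for (i in seq_len(nrow(b))) {
        if (spectrum@lineShape == "lorentzian") {
            hw2 <- (b$fwhm[i] / 2)^2
            out <- out + b$amplitude[i] * hw2 /
                ((wavenumbers - b$center[i])^2 + hw2)
        } else {
            out <- out + b$amplitude[i] *
                exp(-4 * log(2) * ((wavenumbers - b$center[i]) / b$fwhm[i])^2)
        }
    }
    scale <- if (modality == "IR") spectrum@irScale else spectrum@ramanScale
    out * scale
})

.newMap <- function(grid3, species, pixelSize, groundTruth = data.frame()) {
    dimnames(grid3) <- list(NULL, NULL, species)
    new("ConcentrationMap", species = species, grid = grid3,
        pixelSize = pixelSize, groundTruth = groundTruth)
}

#' Spherical-bead phantom
#'
#' Single-species concentration map of a solid sphere: the value at each
#' pixel is the projected chord length of the sphere through the pixel
#' center, normalized to 1 at the bead center (\eqn{\sqrt{1 - (r/R)^2}}),
#' which is the thickness profile an absorption- or scattering-proportional
#' signal sees -- not a flat disk. The grid is forced to an odd number of
#' pixels so one pixel center coincides with the bead center.
#'
#' An axial (X-Z) view is available via \code{plane = "xz"}; for a sphere it
#' is geometrically identical to the lateral view and is tagged in the
#' ground-truth metadata only.
#'
#' @param diameter bead diameter (um), >= \code{pixelSize}.
#' @param pixelSize pixel size (um).
#' @param field field of view (um), > \code{diameter}.
#' @param species species name for the map (default \code{"pmma"}).
#' @param plane \code{"xy"} (lateral, default) or \code{"xz"} (axial).
#' @return a [ConcentrationMap-class].
#' @examples
#' bead <- makeBeadMap(0.5, pixelSize = 0.05, field = 2)
#' max(concGrid(bead))  # 1 at the bead center
#' @export
makeBeadMap <- function(diameter, pixelSize, field = 6 * diameter,
                        species = "pmma", plane = c("xy", "xz")) {
    plane <- match.arg(plane)
    assertScalar(diameter, "diameter"); assertScalar(pixelSize, "pixelSize")
    assertScalar(field, "field")
    if (diameter < pixelSize)
        stop("'diameter' must be >= 'pixelSize'")
    if (field <= diameter)
        stop("'field' must exceed the bead diameter")
    n <- round(field / pixelSize)
    if (n %% 2 == 0) n <- n + 1
    ax <- centeredAxis(n, pixelSize)
    r2 <- outer(ax^2, ax^2, "+")
    R <- diameter / 2
    g <- sqrt(pmax(0, 1 - r2 / R^2))
    .newMap(array(g, c(n, n, 1)), species, pixelSize,
            data.frame(plane = plane, diameter_um = diameter))
}

#' Granular three-species mixture phantom
#'
#' Places \code{nGrains} non-overlapping circular grains in the field and
#' assigns each grain to one of the three species cyclically, so the total
#' amount per species is equal (a 1:1:1 mixture) up to pixelization.
#' Placement uses rejection sampling with a bounded retry count; if a grain
#' cannot be placed the function errors, reporting how many placements were
#' achieved.
#'
#' @param species character(3) of species names.
#' @param nGrains number of grains, >= 1.
#' @param grainSize grain diameter (um).
#' @param pixelSize pixel size (um).
#' @param field field of view (um).
#' @param seed integer seed (placement is bit-reproducible given the seed).
#' @param maxRetries placement attempts per grain before giving up.
#' @return a [ConcentrationMap-class] with one grid per species; the
#'   ground-truth table lists grain centers, diameter, and species.
#' @export
makeMixtureMap <- function(species, nGrains, grainSize, pixelSize, field,
                           seed = 1L, maxRetries = 1000L) {
    if (length(species) != 3L)
        stop("'species' must name exactly three species")
    if (nGrains < 1L) stop("'nGrains' must be >= 1")
    assertScalar(grainSize, "grainSize"); assertScalar(field, "field")
    assertScalar(pixelSize, "pixelSize")
    n <- round(field / pixelSize)
    ax <- (seq_len(n) - 1) * pixelSize  # top-left pixel-center origin
    centers <- matrix(NA_real_, nGrains, 2)
    R <- grainSize / 2
    withSeed(seed, {
        for (i in seq_len(nGrains)) {
            ok <- FALSE
            for (try in seq_len(maxRetries)) {
                cand <- stats::runif(2, min = R, max = field - R)
                # snap to pixel centers: every same-sized grain then covers
                # an identical pixel pattern, making the per-species totals
                # exactly equal by construction
                cand <- pmin(pmax(round(cand / pixelSize) * pixelSize, R),
                             field - R)
                if (i == 1L || all(sqrt(colSums(
                        (t(centers[seq_len(i - 1), , drop = FALSE]) -
                         cand)^2)) >= grainSize)) {
                    centers[i, ] <- cand; ok <- TRUE; break
                }
            }
            if (!ok)
                stop(sprintf(
                    "could not place grain %d of %d without overlap (%d placed)",
                    i, nGrains, i - 1L))
        }
    })
    sp <- species[((seq_len(nGrains) - 1L) %% 3L) + 1L]
    grid <- array(0, c(n, n, 3))
    for (i in seq_len(nGrains)) {
        k <- match(sp[i], species)
        d2 <- outer((ax - centers[i, 2])^2, (ax - centers[i, 1])^2, "+")
        grid[, , k] <- grid[, , k] + (d2 <= R^2)
    }
    .newMap(grid, species, pixelSize,
            data.frame(x_um = centers[, 1], y_um = centers[, 2],
                       diameter_um = grainSize, species = sp))
}

#' Droplet-field phantom with ground truth
#'
#' Renders a field of droplet-like objects and returns both the map and the
#' exact ground-truth table, so droplet-extraction recall can be scored
#' against construction. A fraction \code{circularFraction} of the objects
#' are disks; the rest are elongated blobs (ellipses with aspect ratio
#' \code{aspect} >= 3 and the same area as the disk of their nominal
#' diameter), which a circularity filter should reject. Objects are placed
#' by rejection sampling without merging; over-dense requests error.
#'
#' Coordinates in the ground-truth table are micrometers with the origin at
#' the center of pixel (1,1) (top-left), x along columns, y along rows.
#'
#' @param nDroplets number of objects (0 allowed: empty map, empty table).
#' @param sizeMean,sizeSd diameter distribution (um), positive mean.
#' @param intensityMean,intensitySd per-object intensity distribution.
#' @param circularFraction proportion of circular objects in [0, 1].
#' @param pixelSize pixel size (um).
#' @param field field of view (um).
#' @param seed integer seed.
#' @param species species name (default \code{"lipid"}).
#' @param aspect axis ratio of elongated blobs (>= 3).
#' @param maxRetries placement attempts per object.
#' @return a [ConcentrationMap-class]; \code{groundTruth(map)} has columns
#'   \code{x_um, y_um, diameter_um, intensity, shape, theta}.
#' @export
makeDropletField <- function(nDroplets, sizeMean = 1.0, sizeSd = 0.2,
                             intensityMean = 1.0, intensitySd = 0.1,
                             circularFraction = 1.0, pixelSize = 0.2,
                             field = 30, seed = 1L, species = "lipid",
                             aspect = 3.5, maxRetries = 1000L) {
    if (nDroplets < 0) stop("'nDroplets' must be >= 0")
    if (circularFraction < 0 || circularFraction > 1)
        stop("'circularFraction' must be in [0, 1]")
    if (sizeMean <= 0 || intensityMean <= 0)
        stop("size and intensity distributions must have positive means")
    if (aspect < 3) stop("'aspect' must be >= 3 for elongated blobs")
    n <- round(field / pixelSize)
    ax <- (seq_len(n) - 1) * pixelSize
    empty <- data.frame(x_um = numeric(), y_um = numeric(),
                        diameter_um = numeric(), intensity = numeric(),
                        shape = character(), theta = numeric())
    if (nDroplets == 0L)
        return(.newMap(array(0, c(n, n, 1)), species, pixelSize, empty))
    nCirc <- round(nDroplets * circularFraction)
    shape <- c(rep("circular", nCirc),
               rep("elongated", nDroplets - nCirc))
    grid <- matrix(0, n, n)
    tab <- NULL
    withSeed(seed, {
        diam <- pmax(stats::rnorm(nDroplets, sizeMean, sizeSd),
                     3 * pixelSize)
        intens <- pmax(stats::rnorm(nDroplets, intensityMean, intensitySd),
                       0.1 * intensityMean)
        theta <- stats::runif(nDroplets, 0, pi)
        # effective placement radius: semimajor axis plus a margin so that
        # rendered objects never touch (no silent merging)
        rEff <- ifelse(shape == "elongated",
                       diam / 2 * sqrt(aspect), diam / 2) + 2 * pixelSize
        centers <- matrix(NA_real_, nDroplets, 2)
        for (i in seq_len(nDroplets)) {
            ok <- FALSE
            for (try in seq_len(maxRetries)) {
                cand <- stats::runif(2, min = rEff[i],
                                     max = field - rEff[i])
                if (i == 1L || all(sqrt(colSums(
                        (t(centers[seq_len(i - 1), , drop = FALSE]) -
                         cand)^2)) >=
                        (rEff[seq_len(i - 1)] + rEff[i]))) {
                    centers[i, ] <- cand; ok <- TRUE; break
                }
            }
            if (!ok)
                stop(sprintf(
                    "droplet density too high: placed %d of %d without merging",
                    i - 1L, nDroplets))
        }
        for (i in seq_len(nDroplets)) {
            dx <- outer(rep(1, n), ax - centers[i, 1])
            dy <- outer(ax - centers[i, 2], rep(1, n))
            if (shape[i] == "circular") {
                inside <- (dx^2 + dy^2) <= (diam[i] / 2)^2
            } else {
                a <- diam[i] / 2 * sqrt(aspect)
                b <- diam[i] / 2 / sqrt(aspect)
                u <- dx * cos(theta[i]) + dy * sin(theta[i])
                v <- -dx * sin(theta[i]) + dy * cos(theta[i])
                inside <- (u / a)^2 + (v / b)^2 <= 1
            }
            grid[inside] <- intens[i]
        }
        tab <- data.frame(x_um = centers[, 1], y_um = centers[, 2],
                           diameter_um = diam, intensity = intens,
                           shape = shape, theta = theta)
    })
    .newMap(array(grid, c(n, n, 1)), species, pixelSize, tab)
}
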