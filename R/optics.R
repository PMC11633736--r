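#' Point-spread-function model
#'
#' Gaussian PSF description for one detection channel. The two channels are
#' configured independently; defaults follow the instrument's deconvolved
#' lateral resolutions (398 nm for the Raman channel, whose pump-Stokes
#' product focus is absorbed into the single configured width, and 561 nm
#' for the photothermal IR channel, whose width implicitly includes
#' thermal-diffusion blur).
#'
#' @param fwhm full width at half maximum, nanometers.
#' @param truncation kernel truncation radius in multiples of sigma.
#' @return list with class \code{"PSFModel"}.
#' @export
psfModel <- function(fwhm, truncation = 4) {
    assertScalar(fwhm, "fwhm"); assertScalar(truncation, "truncation")
    structure(list(fwhm = fwhm, truncation = truncation),
              class = "PSFModel")
}

#' Normalized 2-D Gaussian kernel
#'
#' Rotationally symmetric Gaussian kernel with
#' \code{sigma = fwhm / (2 sqrt(2 log 2))}, truncated at
#' \code{truncation * sigma} and normalized to sum 1 (unit DC gain). If
#' \code{fwhm < pixelSize} the PSF is unresolvable on the grid: a warning is
#' raised and a delta kernel returned.
#'
#' @param fwhm kernel FWHM; any length unit, same as \code{pixelSize}.
#' @param pixelSize grid spacing, same unit as \code{fwhm}.
#' @param truncation truncation radius in sigmas (default 4).
#' @return odd-sized square matrix summing to 1.
#' @export
gaussianKernel <- function(fwhm, pixelSize, truncation = 4) {
    assertScalar(fwhm, "fwhm"); assertScalar(pixelSize, "pixelSize")
    assertScalar(truncation, "truncation")
    if (fwhm < pixelSize) {
        warning("PSF fwhm below pixel size; returning a delta kernel")
        return(matrix(1, 1, 1))
    }
    sigma <- fwhmToSigma(fwhm)
    r <- max(1L, ceiling(truncation * sigma / pixelSize))
    ax <- (-r:r) * pixelSize
    k <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
    k / sum(k)
}

# 2-D convolution with a unit-sum kernel under reflective boundary
# conditions (preserves the spatial integral of the input).
convolveReflect <- function(mat, kernel) {
    kr <- (dim(kernel) - 1) / 2
    if (any(dim(kernel) %% 2 != 1))
        stop("kernel must have odd dimensions")
    if (all(kr == 0)) return(mat * kernel[1, 1])
    padRows <- function(m, k) {
        if (k == 0) return(m)
        k <- min(k, nrow(m) - 1)
        rbind(m[k:1, , drop = FALSE], m,
              m[nrow(m):(nrow(m) - k + 1), , drop = FALSE])
    }
    ky <- min(kr[1], nrow(mat) - 1); kx <- min(kr[2], ncol(mat) - 1)
    if (ky < kr[1] || kx < kr[2]) {
        # field smaller than kernel support: fall back to direct summation
        return(.convolveDirectReflect(mat, kernel))
    }
    p <- padRows(t(padRows(mat, kr[1])), kr[2])
    p <- t(p)
    out <- EBImage::filter2(p, kernel, boundary = "circular")
    out[(kr[1] + 1):(kr[1] + nrow(mat)), (kr[2] + 1):(kr[2] + ncol(mat)),
        drop = FALSE]
}

.convolveDirectReflect <- function(mat, kernel) {
    kr <- (dim(kernel) - 1) / 2
    ny <- nrow(mat); nx <- ncol(mat)
    reflectIdx <- function(i, n) {
        # reflect-without-repeat indexing onto 1..n
        i <- (i - 1) %% (2 * n)
        ifelse(i < n, i + 1, 2 * n - i)
    }
    out <- matrix(0, ny, nx)
    for (dy in -kr[1]:kr[1]) for (dx in -kr[2]:kr[2]) {
        w <- kernel[dy + kr[1] + 1, dx + kr[2] + 1]
        if (w == 0) next
        iy <- reflectIdx(seq_len(ny) + dy, ny)
        ix <- reflectIdx(seq_len(nx) + dx, nx)
        out <- out + w * mat[iy, ix, drop = FALSE]
    }
    out
}

#' Excitation configuration
#'
#' @param irWavenumber mid-IR excitation wavenumber (cm^-1), within the
#'   quantum-cascade-laser tuning range 915--2335 cm^-1.
#' @param ramanWavenumber pump-Stokes detuning (cm^-1).
#' @param pPump,pStokes,pIr average powers of the pump, Stokes and mid-IR
#'   beams (mW), >= 0.
#' @return list with class \code{"ExcitationConfig"}.
#' @export
excitationConfig <- function(irWavenumber = 1750, ramanWavenumber = 2850,
                             pPump = 140, pStokes = 140, pIr = 5) {
    assertScalar(irWavenumber, "irWavenumber")
    assertScalar(ramanWavenumber, "ramanWavenumber")
    assertScalar(pPump, "pPump", strict = FALSE)
    assertScalar(pStokes, "pStokes", strict = FALSE)
    assertScalar(pIr, "pIr", strict = FALSE)
    if (irWavenumber < 915 || irWavenumber > 2335)
        stop("'irWavenumber' outside the QCL range 915-2335 cm^-1")
    structure(list(irWavenumber = irWavenumber,
                   ramanWavenumber = ramanWavenumber,
                   pPump = pPump, pStokes = pStokes, pIr = pIr),
              class = "ExcitationConfig")
}

#' Render focal contrast maps from a concentration map
#'
#' The optical forward model. For each species the concentration grid is
#' blurred by the channel PSF (normalized kernel, reflective boundary) and
#' weighted by the species' band spectrum at the excitation wavenumber:
#' \deqn{\delta_{SRL} = k_{srl}\, P_{pump} P_{Stokes} \sum_s
#'   (C_s \ast PSF_{Raman})\, S^{Raman}_s(\nu_R)}
#' \deqn{\delta_{PT} = k_{pt}\, P_{IR} \sum_s
#'   (C_s \ast PSF_{IR})\, S^{IR}_s(\nu_{IR})}
#' so the SRL contrast is bilinear in pump and Stokes power and the
#' photothermal contrast linear in average mid-IR power, both linear in
#' concentration.
#'
#' \code{deltaPt} is the photothermal fractional transmission-modulation
#' depth at the configured IR power, with the sign convention that IR
#' heating decreases detected transmission (consistent with the observed
#' decrease of the Raman channel under IR illumination); the magnitude maps
#' are signless. Values above 0.2 leave the small-signal regime and trigger
#' a validity warning.
#'
#' @param map a [ConcentrationMap-class].
#' @param library named list of [BandSpectrum-class], one per map species.
#' @param psfRaman,psfIr [psfModel()] for the two channels (FWHM in nm).
#' @param exc an [excitationConfig()].
#' @param gains named numeric \code{c(kSrl=, kPt=)}: \code{kSrl} in
#'   1/mW^2 per unit concentration, \code{kPt} in 1/mW per unit
#'   concentration. The default \code{kPt} corresponds to a 1.8 percent
#'   fractional transmission decrease per milliwatt of average mid-IR power
#'   for unit concentration at a unit-amplitude band.
#' @return a [ContrastPair-class].
#' @export
renderContrast <- function(map, library, psfRaman = psfModel(398),
                           psfIr = psfModel(561), exc = excitationConfig(),
                           gains = c(kSrl = 5e-8, kPt = 0.018)) {
    stopifnot(is(map, "ConcentrationMap"))
    if (!all(map@species %in% names(library)))
        stop("spectral library is missing species: ",
             paste(setdiff(map@species, names(library)), collapse = ", "))
    pxNm <- map@pixelSize * 1e3
    kRaman <- gaussianKernel(psfRaman$fwhm, pxNm, psfRaman$truncation)
    kIr <- gaussianKernel(psfIr$fwhm, pxNm, psfIr$truncation)
    d <- dim(map@grid)
    srl <- matrix(0, d[1], d[2]); pt <- matrix(0, d[1], d[2])
    for (s in seq_along(map@species)) {
        spec <- library[[map@species[s]]]
        rAmp <- evaluateSpectrum(spec, exc$ramanWavenumber, "Raman")
        iAmp <- evaluateSpectrum(spec, exc$irWavenumber, "IR")
        C <- map@grid[, , s]
        if (rAmp > 0) srl <- srl + convolveReflect(C, kRaman) * rAmp
        if (iAmp > 0) pt <- pt + convolveReflect(C, kIr) * iAmp
    }
    srl <- srl * gains[["kSrl"]] * exc$pPump * exc$pStokes
    pt <- pt * gains[["kPt"]] * exc$pIr
    if (max(srl) > 0.2 || max(pt) > 0.2)
        warning("contrast exceeds 0.2: outside the small-signal regime ",
                "assumed by the waveform model")
    # numeric round-off from the FFT-based convolution can leave tiny
    # negative values on zero background
    srl[srl < 0] <- 0; pt[pt < 0] <- 0
    new("ContrastPair", deltaSrl = srl, deltaPt = pt,
        pixelSize = map@pixelSize,
        meta = list(excitation = exc, gains = as.list(gains),
                    psfRamanFwhm = psfRaman$fwhm, psfIrFwhm = psfIr$fwhm))
}
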