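#' Power-normalize an IR channel image
#'
#' IR images are divided by the excitation power delivered at the
#' acquisition wavenumber, removing the source's wavenumber-dependent power
#' envelope before any quantitative comparison across wavenumbers.
#'
#' @param image numeric matrix.
#' @param power either a single positive power (mW) or a data.frame with
#'   columns \code{wavenumber} and \code{power} describing the source power
#'   curve, interpolated linearly at \code{wavenumber}.
#' @param wavenumber acquisition wavenumber (cm^-1), required when
#'   \code{power} is a curve.
#' @return the normalized image (image / power).
#' @export
powerNormalize <- function(image, power, wavenumber = NULL) {
    if (is.data.frame(power)) {
        if (is.null(wavenumber))
            stop("'wavenumber' required with a power curve")
        if (!all(c("wavenumber", "power") %in% names(power)))
            stop("power curve needs columns 'wavenumber' and 'power'")
        p <- stats::approx(power$wavenumber, power$power,
                           xout = wavenumber, rule = 1)$y
        if (is.na(p))
            stop("acquisition wavenumber outside the power curve")
    } else {
        p <- power
    }
    if (!is.finite(p) || p <= 0)
        stop("reference power must be positive")
    image / p
}

#' Per-pixel non-negative spectral unmixing
#'
#' Solves, at every pixel, the non-negative least-squares problem
#' \eqn{\min_{a \ge 0} \| R a - y \|_2} where \eqn{y} is the vector of
#' channel values at the pixel and \eqn{R} the reference-response matrix
#' (rows = acquisition channels, columns = species). Non-negativity is the
#' physical abundance constraint; an unconstrained least-squares route is
#' available for comparison.
#'
#' @param images 3-D array \code{[y, x, channel]} or list of matrices, one
#'   per acquisition channel.
#' @param refs numeric matrix (channels x species) of reference responses;
#'   must have full column rank and non-negative entries.
#' @param method \code{"nnls"} (default) or \code{"ls"}.
#' @return list with \code{abundance} (\code{[y, x, species]} array) and
#'   \code{residual} (matrix of per-pixel residual norms).
#' @export
unmix <- function(images, refs, method = c("nnls", "ls")) {
    method <- match.arg(method)
    if (is.list(images)) images <- simplify2array(images)
    d <- dim(images)
    if (length(d) != 3L)
        stop("'images' must be a [y, x, channel] array or list of matrices")
    refs <- as.matrix(refs)
    if (d[3] < ncol(refs))
        stop("need at least as many channels as species")
    if (nrow(refs) != d[3])
        stop("nrow(refs) must equal the number of channel images")
    if (any(refs < 0)) stop("reference responses must be >= 0")
    if (qr(refs)$rank < ncol(refs))
        stop("rank-deficient reference matrix")
    ns <- ncol(refs)
    ab <- array(0, c(d[1], d[2], ns))
    res <- matrix(0, d[1], d[2])
    Y <- matrix(aperm(images, c(3, 1, 2)), nrow = d[3])
    if (method == "ls") pinv <- solve(crossprod(refs), t(refs))
    for (p in seq_len(ncol(Y))) {
        y <- Y[, p]
        if (method == "nnls") {
            fit <- pracma::lsqnonneg(refs, y)
            a <- fit$x
        } else {
            a <- as.numeric(pinv %*% y)
        }
        i <- ((p - 1) %% d[1]) + 1
        j <- ((p - 1) %/% d[1]) + 1
        ab[i, j, ] <- a
        res[i, j] <- sqrt(sum((refs %*% a - y)^2))
    }
    if (!is.null(colnames(refs))) dimnames(ab) <-
        list(NULL, NULL, colnames(refs))
    list(abundance = ab, residual = res)
}

#' Pearson correlation between two images
#'
#' Standard Pearson correlation over all pixels of the raw images, used as
#' a (lack-of-)specificity score: lower cross-channel correlation means the
#' two chemical maps carry more distinct information.
#'
#' @param imageA,imageB numeric matrices of the same shape.
#' @param mask optional logical matrix restricting the pixels used.
#' @return correlation coefficient in [-1, 1].
#' @export
pcc <- function(imageA, imageB, mask = NULL) {
    if (!identical(dim(imageA), dim(imageB)))
        stop("images must share dimensions")
    a <- as.vector(imageA); b <- as.vector(imageB)
    if (!is.null(mask)) {
        a <- a[as.vector(mask)]; b <- b[as.vector(mask)]
    }
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("constant image: correlation undefined")
    stats::cor(a, b)
}

#' Ratiometric image
#'
#' Implements the division-stabilized ratio recipe: each input is
#' background-subtracted, normalized to [0, 1] (by its maximum, or by an
#' upper percentile), offset by the constant 1 to avoid abnormal values in
#' divisions near zero, and then the two are divided:
#' \deqn{out = \frac{norm(A - bg_A) + 1}{norm(B - bg_B) + 1}}
#' With max-normalization the output is confined to [0.5, 2] and is
#' invariant to common linear rescaling of both inputs.
#'
#' @param numerator,denominator numeric matrices of the same shape.
#' @param backgroundNum,backgroundDen scalar background levels, or logical
#'   masks whose mean pixel value defines the background.
#' @param normalize \code{"max"} (default) or \code{"percentile"}.
#' @param prob percentile used when \code{normalize = "percentile"}.
#' @return ratio image.
#' @export
ratiometric <- function(numerator, denominator, backgroundNum = 0,
                        backgroundDen = 0,
                        normalize = c("max", "percentile"), prob = 0.99) {
    normalize <- match.arg(normalize)
    if (!identical(dim(numerator), dim(denominator)))
        stop("images must share dimensions")
    normOne <- function(img, bg) {
        if (is.logical(bg)) bg <- mean(img[bg])
        z <- img - bg
        z[z < 0] <- 0
        top <- if (normalize == "max") max(z) else
            stats::quantile(z, prob, names = FALSE)
        if (top <= 0)
            stop("all-background image: nothing to normalize")
        z <- z / top
        if (normalize == "percentile") z[z > 1] <- 1
        z
    }
    (normOne(numerator, backgroundNum) + 1) /
        (normOne(denominator, backgroundDen) + 1)
}

# 8-connected component labelling by iterative minimum-label propagation.
labelComponents <- function(mask) {
    n <- dim(mask)
    lab <- matrix(0L, n[1], n[2])
    lab[mask] <- seq_len(sum(mask))
    if (!any(mask)) return(lab)
    big <- sum(mask) + 1L
    L <- matrix(big, n[1], n[2])
    L[mask] <- lab[mask]
    shift <- function(m, dy, dx) {
        out <- matrix(big, n[1], n[2])
        ys <- max(1, 1 + dy):min(n[1], n[1] + dy)
        xs <- max(1, 1 + dx):min(n[2], n[2] + dx)
        out[ys, xs] <- m[ys - dy, xs - dx]
        out
    }
    repeat {
        M <- L
        for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
                       c(1, -1), c(1, 0), c(1, 1)))
            M <- pmin(M, shift(L, d[1], d[2]))
        M[!mask] <- big
        if (identical(M, L)) break
        L <- M
    }
    L[!mask] <- 0L
    u <- sort(unique(L[L > 0]))
    matrix(match(L, u, nomatch = 0L), n[1], n[2])
}

# Sub-pixel perimeters from the marching-squares isoline of the continuous
# image at the threshold level: returns the summed contour length (in
# pixels) per component label. Because 8-connected components are separated
# by below-threshold pixels, every closed isoline belongs to exactly one
# component (outer boundary or interior hole) and is assigned to it via the
# nearest above-threshold pixel.
contourPerimeters <- function(z, lab, level) {
    n <- dim(z)
    zp <- matrix(0, n[1] + 2, n[2] + 2)
    zp[2:(n[1] + 1), 2:(n[2] + 1)] <- z
    cl <- grDevices::contourLines(seq_len(n[1] + 2), seq_len(n[2] + 2), zp,
                                  levels = level)
    per <- numeric(max(lab))
    for (cc in cl) {
        x <- cc$x - 1; y <- cc$y - 1  # back to unpadded pixel coords
        len <- sum(sqrt(diff(x)^2 + diff(y)^2))
        # assign to the component owning the nearest above-threshold pixel
        found <- 0L
        for (v in seq_along(x)) {
            for (cand in list(c(floor(x[v]), floor(y[v])),
                              c(ceiling(x[v]), floor(y[v])),
                              c(floor(x[v]), ceiling(y[v])),
                              c(ceiling(x[v]), ceiling(y[v])))) {
                if (cand[1] >= 1 && cand[1] <= n[1] &&
                    cand[2] >= 1 && cand[2] <= n[2] &&
                    lab[cand[1], cand[2]] > 0L) {
                    found <- lab[cand[1], cand[2]]
                    break
                }
            }
            if (found > 0L) break
        }
        if (found > 0L) per[found] <- per[found] + len
    }
    per
}

# Cauchy-Crofton perimeter estimate from boundary crossings counted along
# the two axis and two diagonal direction families.
croftonPerimeter <- function(mask, pixel = 1) {
    p <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
    p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
    nr <- nrow(p); nc <- ncol(p)
    nh <- sum(p[, -1] != p[, -nc])
    nv <- sum(p[-1, ] != p[-nr, ])
    nd1 <- sum(p[-1, -1] != p[-nr, -nc])
    nd2 <- sum(p[-1, -nc] != p[-nr, -1])
    (pi / 8) * pixel * (nh + nv + (nd1 + nd2) / sqrt(2))
}

#' Extract droplet-like objects from an image
#'
#' The droplet morphometry recipe: the image is bilinearly interpolated to
#' a 0.1-um pixel grid, background-subtracted, thresholded (Otsu by
#' default), segmented into 8-connected components, and each component is
#' measured (area, centroid, equivalent diameter, mean intensity,
#' circularity \eqn{4\pi A / P^2} with a Cauchy-Crofton perimeter
#' estimate, clipped at 1.05 to absorb discretization overshoot).
#' Components are kept when their circularity lies in
#' \code{circularityRange} and their area reaches that of a disk of
#' \code{minDiameter} -- the minimal size threshold set by the resolution
#' limit of the instrument.
#'
#' @param image numeric matrix.
#' @param pixelSize pixel size of \code{image} (um).
#' @param circularityRange kept circularity interval, default [0.8, 1.0]
#'   (upper bound compared after clipping, so use \code{c(0.8, 1.05)} to
#'   keep slight overshoots; the default keeps values up to 1.0 only).
#' @param minDiameter minimal equivalent diameter (um); default 0.4, about
#'   the Raman-channel resolution limit.
#' @param interpPixel interpolation target pixel size (um), default 0.1.
#' @param threshold \code{"otsu"} or \code{"fixed"}.
#' @param thresholdValue threshold on the background-subtracted image when
#'   \code{threshold = "fixed"}.
#' @param perimeter \code{"contour"} (default): sub-pixel marching-squares
#'   isoline length at the threshold level, which is stable for objects a
#'   few pixels across; or \code{"crofton"}: Cauchy-Crofton crossing-count
#'   estimate on the binary mask, which fluctuates strongly at that scale.
#' @param filter if \code{FALSE}, return all components unfiltered (with
#'   a \code{kept} column instead).
#' @return a droplet table: one row per object with columns \code{label},
#'   \code{y_um}, \code{x_um}, \code{area_um2}, \code{equiv_diameter_um},
#'   \code{perimeter_um}, \code{circularity}, \code{mean_intensity} (and
#'   \code{kept} when \code{filter = FALSE}). Centroid coordinates use the
#'   same origin convention as [ConcentrationMap-class]: micrometers from
#'   the center of the top-left pixel. No components found returns an
#'   empty table, not an error.
#' @export
extractDroplets <- function(image, pixelSize,
                            circularityRange = c(0.8, 1.0),
                            minDiameter = 0.4, interpPixel = 0.1,
                            threshold = c("otsu", "fixed"),
                            thresholdValue = NULL,
                            perimeter = c("contour", "crofton"),
                            filter = TRUE) {
    threshold <- match.arg(threshold)
    perimeter <- match.arg(perimeter)
    assertScalar(pixelSize, "pixelSize")
    assertScalar(interpPixel, "interpPixel")
    emptyTab <- data.frame(label = integer(), y_um = numeric(),
                           x_um = numeric(), area_um2 = numeric(),
                           equiv_diameter_um = numeric(),
                           perimeter_um = numeric(),
                           circularity = numeric(),
                           mean_intensity = numeric())
    f <- pixelSize / interpPixel
    nd <- pmax(2L, round(dim(image) * f))
    z <- if (abs(f - 1) < 1e-12) image else
        EBImage::resize(image, w = nd[1], h = nd[2], filter = "bilinear")
    z <- z - min(z)
    if (max(z) <= 0) return(emptyTab)
    if (threshold == "otsu") {
        th <- EBImage::otsu(EBImage::Image(z / max(z))) * max(z)
    } else {
        if (is.null(thresholdValue))
            stop("'thresholdValue' required for fixed thresholding")
        th <- thresholdValue
    }
    mask <- z > th
    if (!any(mask)) return(emptyTab)
    lab <- labelComponents(mask)
    k <- max(lab)
    rows <- vector("list", k)
    minArea <- pi * (minDiameter / 2)^2
    perims <- if (perimeter == "contour")
        contourPerimeters(z, lab, th) * interpPixel else NULL
    for (i in seq_len(k)) {
        sel <- lab == i
        area <- sum(sel) * interpPixel^2
        per <- if (perimeter == "contour") perims[i] else
            croftonPerimeter(sel, interpPixel)
        if (!is.finite(per) || per <= 0)
            per <- croftonPerimeter(sel, interpPixel)
        circ <- min(4 * pi * area / per^2, 1.05)
        idx <- which(sel, arr.ind = TRUE)
        rows[[i]] <- data.frame(
            label = i,
            y_um = (mean(idx[, 1]) - 1) * interpPixel,
            x_um = (mean(idx[, 2]) - 1) * interpPixel,
            area_um2 = area,
            equiv_diameter_um = 2 * sqrt(area / pi),
            perimeter_um = per,
            circularity = circ,
            mean_intensity = mean(z[sel]))
    }
    tab <- do.call(rbind, rows)
    kept <- tab$circularity >= circularityRange[1] &
        tab$circularity <= circularityRange[2] &
        tab$area_um2 >= minArea
    if (filter) tab[kept, , drop = FALSE] else cbind(tab, kept = kept)
}

#' Two-sample droplet statistics
#'
#' Pooled-variance two-sample t test and two-sided F test of equal
#' variances on a chosen droplet measurement (size or intensity), with the
#' conventional significance star coding (* P < 0.05, ** P < 0.01,
#' *** P < 1e-3, **** P < 1e-4).
#'
#' @param tableA,tableB droplet tables from [extractDroplets()] (or any
#'   data.frame with the measurement column), each with >= 2 rows.
#' @param column measurement column, default \code{"equiv_diameter_um"}.
#' @return list with \code{tStatistic}, \code{tPValue}, \code{tStars},
#'   \code{varStatistic} (F), \code{varPValue}, \code{varStars},
#'   \code{nA}, \code{nB}.
#' @export
dropletStats <- function(tableA, tableB, column = "equiv_diameter_um") {
    for (tb in list(tableA, tableB)) {
        if (!column %in% names(tb))
            stop(sprintf("column '%s' missing from a droplet table", column))
        if (nrow(tb) < 2L) stop("each table needs at least 2 rows")
    }
    a <- tableA[[column]]; b <- tableB[[column]]
    tt <- stats::t.test(a, b, var.equal = TRUE)
    vt <- stats::var.test(a, b)
    stars <- function(p) {
        if (p < 1e-4) "****" else if (p < 1e-3) "***" else
        if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
    }
    list(tStatistic = unname(tt$statistic), tPValue = tt$p.value,
         tStars = stars(tt$p.value),
         varStatistic = unname(vt$statistic), varPValue = vt$p.value,
         varStars = stars(vt$p.value),
         nA = length(a), nB = length(b))
}

#' Gaussian FWHM of a line profile
#'
#' Extracts a row or column profile through a point (default: the image
#' maximum), fits a Gaussian by nonlinear least squares, and returns the
#' fitted full width at half maximum in nanometers.
#'
#' @param image numeric matrix.
#' @param axis \code{"x"} (profile along a row) or \code{"y"}.
#' @param through integer c(row, col); default: position of the maximum.
#' @param pixelSize pixel size (um).
#' @return fitted FWHM (nm).
#' @export
fitProfileFwhm <- function(image, axis = c("x", "y"), through = NULL,
                           pixelSize = 0.05) {
    axis <- match.arg(axis)
    if (max(image) <= min(image))
        stop("flat image: no peak to fit")
    if (is.null(through))
        through <- which(image == max(image), arr.ind = TRUE)[1, ]
    prof <- if (axis == "x") image[through[1], ] else image[, through[2]]
    x <- (seq_along(prof) - 1) * pixelSize * 1e3
    pk <- max(prof)
    above <- prof >= pk / 2
    runs <- rle(above)
    if (sum(runs$values) > 1L)
        stop("profile has multiple dominant peaks; cannot fit a single ",
             "Gaussian (peaks above half maximum: ", sum(runs$values), ")")
    s0 <- max(sum(above) * pixelSize * 1e3 / 2.3548, pixelSize * 1e3)
    fit <- tryCatch(
        minpack.lm::nlsLM(
            prof ~ a * exp(-(x - mu)^2 / (2 * s^2)),
            start = list(a = pk, mu = x[which.max(prof)], s = s0),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e)
            stop("Gaussian profile fit failed: ", conditionMessage(e),
                 " (profile max ", signif(pk, 4), ", start sigma ",
                 signif(s0, 4), " nm)", call. = FALSE))
    sigmaToFwhm(abs(stats::coef(fit)[["s"]]))
}

# Forward model of the bead-profile measurement: Gaussian-fit FWHM (nm) of
# the central line profile of a sphere-projection bead image blurred by a
# Gaussian PSF of the given FWHM (nm).
.modelBeadFwhm <- function(psfFwhmNm, beadDiameterNm, pixelNm = NULL) {
    if (is.null(pixelNm)) pixelNm <- beadDiameterNm / 20
    fieldUm <- (beadDiameterNm + 8 * max(psfFwhmNm, pixelNm)) / 1e3
    bead <- makeBeadMap(beadDiameterNm / 1e3, pixelNm / 1e3, fieldUm)
    img <- concGrid(bead)[, , 1]
    if (psfFwhmNm >= pixelNm) {
        kern <- gaussianKernel(psfFwhmNm, pixelNm)
        img <- convolveReflect(img, kern)
    }
    ctr <- (dim(img) + 1) / 2
    fitProfileFwhm(img, "x", through = ctr, pixelSize = pixelNm / 1e3)
}

#' Deconvolve the finite bead size from a measured profile width
#'
#' Estimates the channel resolution (PSF FWHM) from the Gaussian-fitted
#' FWHM of a bead line profile.
#'
#' The default \code{beadModel = "projection"} numerically inverts the
#' actual measurement chain -- sphere-projection bead profile, Gaussian
#' blur, Gaussian fit -- so imaging a bead and deconvolving recovers the
#' configured PSF width. \code{beadModel = "gaussian"} instead applies the
#' simple quadrature convention \eqn{\sqrt{F_{meas}^2 - D^2}} that treats
#' the bead as a Gaussian of FWHM equal to its diameter; it is retained as
#' the conventional shorthand but is biased low for solid spheres, whose
#' effective Gaussian width is well below their diameter.
#'
#' If the measured width is not larger than the bead contribution the
#' function returns 0 with a warning.
#'
#' @param measuredFwhm measured profile FWHM (nm), > 0.
#' @param beadDiameter bead diameter (nm), >= 0 (0 returns
#'   \code{measuredFwhm} unchanged).
#' @param beadModel \code{"projection"} (default) or \code{"gaussian"}.
#' @param pixelNm grid spacing for the numerical inversion (nm).
#' @return estimated resolution (nm).
#' @examples
#' deconvolveBead(sqrt(398^2 + 500^2), 500, beadModel = "gaussian")  # 398
#' @export
deconvolveBead <- function(measuredFwhm, beadDiameter,
                           beadModel = c("projection", "gaussian"),
                           pixelNm = NULL) {
    beadModel <- match.arg(beadModel)
    assertScalar(measuredFwhm, "measuredFwhm")
    assertScalar(beadDiameter, "beadDiameter", strict = FALSE)
    if (beadDiameter == 0) return(measuredFwhm)
    if (beadModel == "gaussian") {
        q <- measuredFwhm^2 - beadDiameter^2
        if (q <= 0) {
            warning("measured width not larger than the bead size; ",
                    "returning 0")
            return(0)
        }
        return(sqrt(q))
    }
    if (is.null(pixelNm)) pixelNm <- beadDiameter / 20
    lo <- pixelNm
    baseline <- .modelBeadFwhm(lo, beadDiameter, pixelNm)
    if (measuredFwhm <= baseline) {
        warning("measured width not larger than the bare bead profile; ",
                "returning 0")
        return(0)
    }
    hi <- 2 * measuredFwhm
    f <- function(F) .modelBeadFwhm(F, beadDiameter, pixelNm) - measuredFwhm
    stats::uniroot(f, c(lo, hi), tol = 0.5)$root
}
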