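test_that("power normalization divides by the source power", {
    img <- matrix(1:6, 2, 3)
    expect_equal(powerNormalize(img, 1), img)
    expect_equal(powerNormalize(img, 2), img / 2)
    # wavenumber-dependent power curve round-trips a flat response
    curve <- data.frame(wavenumber = seq(900, 2400, by = 100),
                        power = 2 + sin(seq(900, 2400, by = 100) / 200))
    nu <- 1550
    p <- approx(curve$wavenumber, curve$power, nu)$y
    raw <- img * p
    expect_equal(powerNormalize(raw, curve, wavenumber = nu), img)
    expect_error(powerNormalize(img, 0), "positive")
    expect_error(powerNormalize(img, curve, wavenumber = 500), "outside")
})

test_that("non-negative unmixing recovers pure pixels and clips with identity refs", {
    refs <- matrix(c(1, 0, 0.2, 0, 1, 0.3), nrow = 3)
    # two pixels: one pure in each species
    px <- aperm(array(c(refs[, 1], refs[, 2]), c(3, 1, 2)), c(2, 3, 1))
    um <- unmix(px, refs)
    expect_equal(um$abundance[1, 1, ], c(1, 0), tolerance = 1e-10)
    expect_equal(um$abundance[1, 2, ], c(0, 1), tolerance = 1e-10)

    id <- diag(2)
    # pixel (1,1): channels (0.4, 0.7); pixel (1,2): channels (-0.1, 0.2)
    y <- array(c(0.4, -0.1, 0.7, 0.2), c(1, 2, 2))
    umId <- unmix(y, id)
    expect_equal(umId$abundance[1, 1, ], c(0.4, 0.7))
    expect_equal(umId$abundance[1, 2, ], c(0, 0.2))  # negative clipped

    expect_error(unmix(y, matrix(c(1, 1, 2, 2), 2, 2)), "rank")
    expect_error(unmix(y[, , 1, drop = FALSE], id), "channels")
})

test_that("unmixing the tertiary mixture recovers abundances within 2% (noiseless)", {
    sp <- c("palmitic_acid", "diphdy", "tpp")
    map <- makeMixtureMap(sp, 21, grainSize = 2.5, pixelSize = 0.25,
                          field = 25, seed = 1)
    lib <- presetLibrary(sp)
    imgs <- lapply(mixtureChannels(), function(ch) {
        ip <- scanImage(map, lib, exc = mixtureExcitation(ch), path = "fast")
        if (ch$mod == "IR") irImage(ip) else ramanImage(ip)
    })
    refs <- mixtureRefs(sp, lib)
    um <- unmix(imgs, refs)
    err <- mean(abs(um$abundance - concGrid(map)))
    expect_lt(err, 0.02)

    # graceful degradation: abundance error grows monotonically with noise
    set.seed(21)
    errs <- vapply(c(0, 0.02, 0.08), function(s) {
        noisy <- lapply(imgs, function(m)
            m * (1 + matrix(rnorm(length(m), sd = s), nrow(m))))
        mean(abs(unmix(noisy, refs)$abundance - concGrid(map)))
    }, numeric(1))
    expect_true(all(diff(errs) > 0))
})

test_that("unmixed abundance maps are less correlated than single-modality pairs", {
    sp <- c("palmitic_acid", "diphdy", "tpp")
    map <- makeMixtureMap(sp, 21, grainSize = 2.5, pixelSize = 0.25,
                          field = 25, seed = 1)
    lib <- presetLibrary(sp)
    imgs <- lapply(mixtureChannels(), function(ch) {
        ip <- scanImage(map, lib, exc = mixtureExcitation(ch), path = "fast")
        if (ch$mod == "IR") irImage(ip) else ramanImage(ip)
    })
    um <- unmix(imgs, mixtureRefs(sp, lib))
    ab <- um$abundance
    maxUnmixed <- max(abs(c(pcc(ab[, , 1], ab[, , 2]),
                            pcc(ab[, , 1], ab[, , 3]),
                            pcc(ab[, , 2], ab[, , 3]))))
    # single-modality image pairs at shared-band wavenumbers
    irPair <- pcc(imgs[[1]], imgs[[3]])     # IR 1477 vs IR 1700
    ramanPair <- pcc(imgs[[2]], imgs[[4]])  # Raman 1593 vs Raman 2216
    expect_lt(maxUnmixed, irPair)
    expect_lt(maxUnmixed, ramanPair)
})

test_that("Pearson correlation handles the canonical cases", {
    a <- matrix(c(0, 1, 2, 3), 2, 2)
    expect_equal(pcc(a, a), 1)
    expect_equal(pcc(a, -a), -1)
    b <- matrix(c(1, 0, 3, 2), 2, 2)
    expect_equal(pcc(a, b), 0.6)  # hand-computed covariance/sigma product
    expect_error(pcc(a, matrix(1, 2, 2)), "constant")
    expect_error(pcc(a, matrix(1, 3, 3)), "dimensions")
})

test_that("ratiometric recipe: normalize, offset by one, divide", {
    a <- matrix(c(0, 5, 10), 3, 1)
    b <- matrix(c(10, 10, 10), 3, 1)
    expect_equal(ratiometric(a, a), matrix(1, 3, 1))
    # hand calculation: norm(a) = (0, .5, 1); b is constant above bg 5:
    # norm(b - 5) = (1, 1, 1)
    out <- ratiometric(a, b, backgroundNum = 0, backgroundDen = 5)
    expect_equal(out, matrix((c(0, 0.5, 1) + 1) / 2, 3, 1))
    # bounds and invariance to common linear rescaling
    set.seed(3)
    x <- matrix(runif(64), 8, 8); y <- matrix(runif(64), 8, 8)
    r1 <- ratiometric(x, y)
    expect_true(all(r1 >= 0.5 & r1 <= 2))
    expect_equal(ratiometric(7 * x, 7 * y), r1)
    expect_error(ratiometric(matrix(0, 2, 2), matrix(1, 2, 2)),
                 "background")
})

test_that("droplet extraction keeps disks and rejects elongated blobs", {
    # three disks and one aspect-4 blob above threshold -> three rows
    px <- 0.1
    img <- matrix(0, 80, 80)
    ax <- (seq_len(80) - 1) * px
    disk <- function(cx, cy, d)
        outer((ax - cy)^2, (ax - cx)^2, "+") <= (d / 2)^2
    img[disk(2, 2, 1.2)] <- 1
    img[disk(5.5, 2.5, 0.9)] <- 1.2
    img[disk(2.5, 5.5, 1.5)] <- 0.8
    u <- outer(rep(1, 80), ax - 5.8); v <- outer(ax - 5.8, rep(1, 80))
    img[(u / 1.2)^2 + (v / 0.3)^2 <= 1] <- 1  # aspect 4 ellipse
    tab <- extractDroplets(img, pixelSize = px)
    expect_equal(nrow(tab), 3)
    expect_true(all(tab$circularity >= 0.8))

    expect_equal(nrow(extractDroplets(matrix(0, 20, 20), 0.1)), 0)
})

test_that("droplet-field recall is >= 0.9 with no elongated objects retained", {
    fld <- makeDropletField(50, circularFraction = 0.8, seed = 3)
    gt <- groundTruth(fld)
    tab <- extractDroplets(concGrid(fld)[, , 1], pixelSize(fld))
    circ <- gt[gt$shape == "circular", ]
    hit <- vapply(seq_len(nrow(circ)), function(i)
        any(sqrt((tab$y_um - circ$y_um[i])^2 +
                 (tab$x_um - circ$x_um[i])^2) < 0.5), logical(1))
    expect_gte(mean(hit), 0.9)
    el <- gt[gt$shape == "elongated", ]
    near <- vapply(seq_len(nrow(el)), function(i)
        any(sqrt((tab$y_um - el$y_um[i])^2 +
                 (tab$x_um - el$x_um[i])^2) < 0.3), logical(1))
    expect_equal(sum(near), 0)
})

test_that("component measurement agrees with the brute-force oracle on small images", {
    set.seed(14)
    for (rep in 1:4) {
        # random smooth blob image <= 64 x 64
        n <- sample(40:64, 1)
        img <- matrix(0, n, n)
        for (k in 1:6) {
            cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8)
            s <- runif(1, 1.5, 4)
            img <- img + exp(-(outer((seq_len(n) - cy)^2,
                                     (seq_len(n) - cx)^2, "+")) / (2 * s^2))
        }
        tab <- extractDroplets(img, pixelSize = 0.1,
                               circularityRange = c(0, 1.05),
                               minDiameter = 0, filter = FALSE)
        # oracle: independent flood fill on the same mask
        z <- img - min(img)
        th <- EBImage::otsu(EBImage::Image(z / max(z))) * max(z)
        lab <- floodLabel(z > th)
        expect_equal(nrow(tab), max(lab))
        areas <- sort(as.numeric(table(lab[lab > 0])) * 0.1^2)
        expect_equal(sort(tab$area_um2), areas, tolerance = 1e-12)
        # single-object images: perimeter vs independent marching squares
        if (max(lab) == 1) {
            expect_equal(tab$perimeter_um,
                         marchingLength(z, th) * 0.1, tolerance = 0.05)
        }
    }
    # explicit single-disk perimeter cross-check
    ax <- seq_len(60)
    one <- (outer((ax - 30)^2, (ax - 30)^2, "+") <= 12^2) * 1.0
    t1 <- extractDroplets(one, pixelSize = 0.1, circularityRange = c(0, 1.05),
                          minDiameter = 0, filter = FALSE)
    expect_equal(nrow(t1), 1)
    z <- one - min(one)
    th <- EBImage::otsu(EBImage::Image(z / max(z))) * max(z)
    expect_equal(t1$perimeter_um, marchingLength(z, th) * 0.1,
                 tolerance = 0.02)
})

test_that("droplet statistics reproduce textbook pooled-t results", {
    tA <- data.frame(equiv_diameter_um = c(1, 2, 3))
    tB <- data.frame(equiv_diameter_um = c(4, 5, 6))
    st <- dropletStats(tA, tB)
    expect_equal(st$tStatistic, -3.674235, tolerance = 1e-6)
    expect_equal(st$tPValue, 0.02131164, tolerance = 1e-6)
    expect_equal(st$tStars, "*")
    expect_equal(st$nA, 3)

    same <- dropletStats(tA, tA)
    expect_equal(same$tStatistic, 0)
    expect_equal(same$tPValue, 1)
    expect_equal(same$varStatistic, 1)

    expect_error(dropletStats(tA, data.frame(x = 1:3)), "missing")
    expect_error(dropletStats(tA[1, , drop = FALSE], tB), "2 rows")
})

test_that("t-test rejection rates match the closed-form power curve", {
    nRep <- 400; n <- 100
    alpha <- 0.05
    tcrit <- qt(1 - alpha / 2, df = 2 * n - 2)
    for (delta in c(0, 0.3)) {
        set.seed(1000 + round(delta * 10))
        rej <- mean(vapply(seq_len(nRep), function(r) {
            a <- rnorm(n); b <- rnorm(n, mean = delta)
            dropletStats(data.frame(equiv_diameter_um = a),
                         data.frame(equiv_diameter_um = b))$tPValue < alpha
        }, logical(1)))
        ncp <- delta / sqrt(2 / n)
        power <- 1 - pt(tcrit, 2 * n - 2, ncp) + pt(-tcrit, 2 * n - 2, ncp)
        ci <- 3 * sqrt(power * (1 - power) / nRep) + 1e-3
        expect_lt(abs(rej - power), ci)
    }
})

test_that("profile fitting and bead deconvolution recover configured widths", {
    # rendered Gaussian of FWHM 500 nm
    px <- 0.025
    ax <- (seq_len(101) - 51) * px * 1e3
    sig <- 500 / (2 * sqrt(2 * log(2)))
    img <- exp(-outer(ax^2, ax^2, "+") / (2 * sig^2))
    expect_equal(fitProfileFwhm(img, "x", pixelSize = px), 500,
                 tolerance = 5 / 500)

    # sphere-projection (x) Gaussian profile vs interpolated half-max width
    bead <- makeBeadMap(0.5, 0.025, 2.5)
    g <- concGrid(bead)[, , 1]
    k <- gaussianKernel(561, 25)
    blur <- inspiresim:::convolveReflect(g, k)
    fw <- fitProfileFwhm(blur, "x", pixelSize = 0.025)
    prof <- blur[(nrow(blur) + 1) / 2, ]
    x <- (seq_along(prof) - 1) * 25
    half <- max(prof) / 2
    above <- which(prof >= half)
    xl <- approx(prof[c(min(above) - 1, min(above))],
                 x[c(min(above) - 1, min(above))], xout = half)$y
    xr <- approx(prof[c(max(above), max(above) + 1)],
                 x[c(max(above), max(above) + 1)], xout = half)$y
    expect_lt(abs(fw - (xr - xl)) / (xr - xl), 0.03)

    expect_error(fitProfileFwhm(matrix(1, 5, 5), "x"), "flat")

    # quadrature convention and its algebraic inversion
    expect_equal(deconvolveBead(300, 0), 300)
    expect_equal(deconvolveBead(sqrt(398^2 + 500^2), 500,
                                beadModel = "gaussian"), 398)
    expect_warning(r0 <- deconvolveBead(400, 500, beadModel = "gaussian"),
                   "returning 0")
    expect_equal(r0, 0)
})

test_that("imaging a bead and deconvolving recovers the configured PSF widths", {
    bead <- makeBeadMap(0.5, 0.05, 4)
    lib <- pmmaLib()
    ip <- scanImage(bead, lib, psfRaman = psfModel(398),
                    psfIr = psfModel(561),
                    exc = excitationConfig(1730, 2957, pIr = 1))
    fwR <- fitProfileFwhm(ramanImage(ip), "x", pixelSize = 0.05)
    fwI <- fitProfileFwhm(irImage(ip), "x", pixelSize = 0.05)
    expect_lt(abs(deconvolveBead(fwR, 500) - 398) / 398, 0.05)
    expect_lt(abs(deconvolveBead(fwI, 500) - 561) / 561, 0.05)
})
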