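# Independent reference implementations used as test oracles. These stay
# deliberately separate from the package's code paths: flood fill instead
# of label propagation, direct DFT projections instead of the lock-in, and
# a from-scratch marching-squares tracer for perimeters.

# Complex amplitude (2|c|) of the component of x at frequency f.
fftAmplitude <- function(x, f, fs) {
    n <- length(x)
    t <- (seq_len(n) - 1) / fs
    2 * Mod(mean(x * exp(-2i * pi * f * t)))
}

# Local-maximum peak finding on a PSD with a minimum separation (Hz).
topPeaks <- function(ps, k = 3, minSep = 50e3, fMax = Inf) {
    d <- ps[ps$frequency > 0 & ps$frequency <= fMax, ]
    d <- d[order(-d$psd), ]
    picked <- numeric(0)
    for (i in seq_len(nrow(d))) {
        if (all(abs(d$frequency[i] - picked) > minSep)) {
            picked <- c(picked, d$frequency[i])
            if (length(picked) == k) break
        }
    }
    sort(picked)
}

# Queue-based 8-connected flood-fill labelling (independent of the
# package's label-propagation implementation).
floodLabel <- function(mask) {
    n <- dim(mask)
    lab <- matrix(0L, n[1], n[2])
    nextLab <- 0L
    for (start in which(mask)) {
        if (lab[start] != 0L) next
        nextLab <- nextLab + 1L
        queue <- start
        lab[start] <- nextLab
        while (length(queue)) {
            p <- queue[length(queue)]
            queue <- queue[-length(queue)]
            i <- ((p - 1L) %% n[1]) + 1L
            j <- ((p - 1L) %/% n[1]) + 1L
            for (di in -1:1) for (dj in -1:1) {
                ii <- i + di; jj <- j + dj
                if (ii >= 1 && ii <= n[1] && jj >= 1 && jj <= n[2] &&
                    mask[ii, jj] && lab[ii, jj] == 0L) {
                    lab[ii, jj] <- nextLab
                    queue <- c(queue, (jj - 1L) * n[1] + ii)
                }
            }
        }
    }
    lab
}

# From-scratch marching-squares contour length of z at `level`, total over
# all contours (used to cross-check per-component perimeters on images
# with a single object).
marchingLength <- function(z, level) {
    n <- dim(z)
    zp <- matrix(0, n[1] + 2, n[2] + 2)
    zp[2:(n[1] + 1), 2:(n[2] + 1)] <- z
    total <- 0
    interp <- function(va, vb) (level - va) / (vb - va)
    for (i in seq_len(nrow(zp) - 1)) for (j in seq_len(ncol(zp) - 1)) {
        v <- c(zp[i, j], zp[i + 1, j], zp[i + 1, j + 1], zp[i, j + 1])
        above <- v > level
        if (all(above) || all(!above)) next
        # crossing points on the 4 cell edges, in (row, col) coordinates
        pts <- list()
        if (xor(above[1], above[2]))
            pts <- c(pts, list(c(i + interp(v[1], v[2]), j)))
        if (xor(above[2], above[3]))
            pts <- c(pts, list(c(i + 1, j + interp(v[2], v[3]))))
        if (xor(above[4], above[3]))
            pts <- c(pts, list(c(i + interp(v[4], v[3]), j + 1)))
        if (xor(above[1], above[4]))
            pts <- c(pts, list(c(i, j + interp(v[1], v[4]))))
        if (length(pts) == 2) {
            total <- total +
                sqrt(sum((pts[[1]] - pts[[2]])^2))
        } else if (length(pts) == 4) {
            # saddle: two segments; pairing choice changes length little
            total <- total +
                sqrt(sum((pts[[1]] - pts[[2]])^2)) +
                sqrt(sum((pts[[3]] - pts[[4]])^2))
        }
    }
    total
}

# Closed-form periodic steady state of the exponential rise/decay envelope.
envelopeFixedPointOracle <- function(peak, tp, toff, tauRise, tauDecay) {
    a <- exp(-tp / tauRise)
    b <- exp(-toff / tauDecay)
    mMax <- peak * (1 - a) / (1 - a * b)
    list(mMax = mMax, mMin = mMax * b)
}

# Shared small fixtures
pmmaLib <- function() presetLibrary("pmma")

mixtureChannels <- function() list(
    list(nu = 1477, mod = "IR"), list(nu = 1593, mod = "Raman"),
    list(nu = 1700, mod = "IR"), list(nu = 2216, mod = "Raman"))

mixtureExcitation <- function(ch) {
    if (ch$mod == "IR")
        excitationConfig(irWavenumber = ch$nu, ramanWavenumber = 2850)
    else excitationConfig(irWavenumber = 1750, ramanWavenumber = ch$nu)
}

# Channel responses of unit uniform concentration, used as unmixing refs.
mixtureRefs <- function(species, lib, pixelSize = 0.25) {
    chans <- mixtureChannels()
    refs <- matrix(0, length(chans), length(species),
                   dimnames = list(NULL, species))
    for (i in seq_along(chans)) for (s in seq_along(species)) {
        um <- methods::new("ConcentrationMap", species = species[s],
                           grid = array(1, c(5, 5, 1)),
                           pixelSize = pixelSize)
        ip <- scanImage(um, lib, exc = mixtureExcitation(chans[[i]]),
                        path = "fast")
        refs[i, s] <- (if (chans[[i]]$mod == "IR") irImage(ip)
                       else ramanImage(ip))[3, 3]
    }
    refs
}
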