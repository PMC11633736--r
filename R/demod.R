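#' Software lock-in configuration
#'
#' @param fRef reference frequency (Hz).
#' @param tau low-pass filter time constant (s); default is a tenth of the
#'   trace duration at demodulation time.
#' @param order number of cascaded single-pole low-pass stages (default 4,
#'   an RC^4-like response).
#' @param output \code{"magnitude"} (default), \code{"in-phase"} or
#'   \code{"quadrature"}.
#' @return list with class \code{"LockinConfig"}.
#' @export
lockinConfig <- function(fRef, tau = NULL, order = 4L,
                         output = c("magnitude", "in-phase", "quadrature")) {
    assertScalar(fRef, "fRef")
    if (!is.null(tau)) assertScalar(tau, "tau")
    if (order < 1L) stop("'order' must be >= 1")
    structure(list(fRef = fRef, tau = tau, order = as.integer(order),
                   output = match.arg(output)),
              class = "LockinConfig")
}

# One cascaded single-pole low-pass pass. The cascade is warmed on a
# cyclic prefix of the input (treating the dwell as one period of a
# periodic signal) so the stages enter the real samples near their
# periodic steady state; stages are additionally initialized at the input
# mean and a settling interval is discarded by the caller.
.cascadeLowpass <- function(x, alpha, order, warm = 0L) {
    n <- length(x)
    warm <- min(warm, n)
    if (warm > 0L) x <- c(x[(n - warm + 1L):n], x)
    for (i in seq_len(order))
        x <- as.numeric(stats::filter(alpha * x, 1 - alpha,
                                      method = "recursive",
                                      init = mean(x)))
    if (warm > 0L) x <- x[(warm + 1L):(warm + n)]
    x
}

#' Software lock-in demodulation
#'
#' Multiplies the trace by cosine and sine references at \code{fRef}
#' (phase 0 at t = 0), low-passes each quadrature with the cascaded
#' single-pole filter, discards a settling interval of five time constants
#' and averages the remainder. The magnitude output
#' \eqn{2\sqrt{I^2 + Q^2}} is calibrated so a pure cosine of amplitude A at
#' the reference frequency returns A (component amplitude, not RMS).
#'
#' @param trace a [TimeTrace-class] (or numeric vector with \code{fs}).
#' @param cfg a [lockinConfig()].
#' @param fs sample rate, required when \code{trace} is a bare vector.
#' @return demodulated value per the configured output selector.
#' @examples
#' fs <- 64e6; t <- (0:9999) / fs
#' tr <- new("TimeTrace", samples = 0.3 * (1 + cos(2 * pi * 2e6 * t)) / 2,
#'           sampleRate = fs)
#' lockin(tr, lockinConfig(2e6))  # ~0.15/... amplitude of the 2 MHz cosine
#' @export
lockin <- function(trace, cfg, fs = NULL) {
    if (is(trace, "TimeTrace")) {
        x <- trace@samples; fs <- trace@sampleRate
    } else {
        x <- as.numeric(trace)
        if (is.null(fs)) stop("'fs' required for a bare numeric trace")
    }
    n <- length(x)
    if (n == 0L) stop("empty trace")
    if (cfg$fRef >= fs / 2)
        stop("reference frequency must be below the Nyquist frequency")
    tau <- if (is.null(cfg$tau)) n / fs / 10 else cfg$tau
    settle <- ceiling(5 * tau * fs)
    if (settle >= n)
        stop("settling interval (5 time constants) exceeds the trace length")
    t <- (seq_len(n) - 1) / fs
    w <- 2 * pi * cfg$fRef * t
    dt <- 1 / fs
    alpha <- dt / (tau + dt)
    # AC-coupled input (as in the physical detection path): removing the
    # trace mean keeps the large dc term from ringing through the filter's
    # settling transient; it does not affect any nonzero-frequency component
    x <- x - mean(x)
    I <- .cascadeLowpass(x * cos(w), alpha, cfg$order, warm = settle)
    Q <- .cascadeLowpass(x * sin(w), alpha, cfg$order, warm = settle)
    keep <- (settle + 1):n
    Im <- mean(I[keep]); Qm <- mean(Q[keep])
    switch(cfg$output,
           "magnitude" = 2 * sqrt(Im^2 + Qm^2),
           "in-phase" = 2 * Im,
           "quadrature" = 2 * Qm)
}

#' Mean (dc) trace level
#'
#' Arithmetic mean of the samples: the total-probe-photons observable whose
#' linear dependence on mid-IR power tracks the photothermal modulation.
#'
#' @param trace a [TimeTrace-class] or numeric vector.
#' @return mean intensity.
#' @export
dcLevel <- function(trace) {
    x <- if (is(trace, "TimeTrace")) trace@samples else as.numeric(trace)
    if (length(x) == 0L) stop("empty trace")
    mean(x)
}

#' Welch power spectral density
#'
#' Welch-averaged one-sided periodogram with a Hann window. The density
#' scaling is such that the integral of the PSD over frequency equals the
#' (window-weighted) mean square of the signal, segment-averaged, to within
#' the Welch approximation.
#'
#' @param trace a [TimeTrace-class] or numeric vector.
#' @param segment segment length in seconds (default 0.2 ms, capped at the
#'   trace length).
#' @param overlap segment overlap proportion in [0, 1) (default 0.5).
#' @param fs sample rate for bare numeric traces.
#' @param detrend \code{"mean"} (default) removes each segment's mean
#'   before windowing, emulating ac-coupled detection and keeping the dc
#'   term's leakage out of the low-frequency bins; \code{"none"} keeps the
#'   raw segments (use this when checking Parseval consistency against the
#'   raw mean square).
#' @return data.frame with columns \code{frequency} (Hz) and \code{psd}
#'   (power per Hz).
#' @export
powerSpectrum <- function(trace, segment = NULL, overlap = 0.5, fs = NULL,
                          detrend = c("mean", "none")) {
    detrend <- match.arg(detrend)
    if (is(trace, "TimeTrace")) {
        x <- trace@samples; fs <- trace@sampleRate
        fIr <- tryCatch(trace@meta$train$fIr, error = function(e) NULL)
    } else {
        x <- as.numeric(trace); fIr <- NULL
        if (is.null(fs)) stop("'fs' required for a bare numeric trace")
    }
    n <- length(x)
    # default 0.2-ms segments: 5-kHz bins, so the 100-kHz comb falls on
    # exact bins while segments stay short enough to average
    nseg <- if (is.null(segment)) min(n, round(2e-4 * fs))
        else round(segment * fs)
    if (nseg > n) stop("segment longer than the trace")
    if (nseg < 8L) stop("segment too short")
    if (!is.null(fIr) && fs / nseg > fIr / 2)
        warning("segment too short to resolve the IR modulation frequency")
    step <- max(1L, floor(nseg * (1 - overlap)))
    starts <- seq(1L, n - nseg + 1L, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)
    norm <- fs * sum(w^2)
    nf <- floor(nseg / 2) + 1L
    acc <- numeric(nf)
    for (s in starts) {
        seg <- x[s:(s + nseg - 1L)]
        if (detrend == "mean") seg <- seg - mean(seg)
        X <- stats::fft(seg * w)
        acc <- acc + (Mod(X[seq_len(nf)])^2) / norm
    }
    psd <- acc / length(starts)
    # one-sided: double everything except dc (and Nyquist when nseg even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nf] <- 1
    data.frame(frequency = (seq_len(nf) - 1) * fs / nseg, psd = psd * dbl)
}

# Analytic (noiseless) demodulated amplitudes for given contrast values:
# the fast path of the virtual scan. Derived by projecting the pulse-energy
# sequence onto the two references; agrees with the full waveform +
# lock-in route to within the lock-in's averaging accuracy. Vectorized in
# (deltaSrl, deltaPt).
.fastChannelAmplitudes <- function(deltaSrl, deltaPt, cfg, th, E0 = 1) {
    spp <- cfg$sampleRate / cfg$fProbe
    sh <- envelopeShape(cfg, th)
    ratio <- round(cfg$fProbe / cfg$fStokesMod)
    k <- seq_len(ratio) - 1
    gAmp <- 2 * Mod(sum(rep(c(1, 0), each = ratio / 2) *
                        exp(-2i * pi * k / ratio)) / ratio)
    ir <- (E0 / spp) * (1 - deltaSrl / 2) * deltaPt * sh$fundamental
    raman <- (E0 / spp) * deltaSrl * gAmp * (1 - deltaPt * sh$mean)
    list(ir = ir, raman = raman)
}

#' Virtual scan: assemble co-registered IR and Raman images
#'
#' For each pixel of the concentration map the forward model renders the
#' two contrast values, one probe waveform is synthesized for the pixel
#' dwell, and both channels are demodulated from that single trace (100 kHz
#' for IR, 20 MHz for Raman) -- the simultaneity guarantee of single-probe
#' detection. Per-pixel noise seeds are derived deterministically from the
#' global seed and the pixel index, so noisy scans are bit-reproducible.
#'
#' The default \code{path = "fast"} skips waveform synthesis and returns
#' the analytic demodulated amplitudes (noiseless); it agrees with the full
#' waveform route to better than 1 percent and is the sensible choice for
#' large images. \code{path = "full"} synthesizes and demodulates every
#' pixel and honors the noise configuration.
#'
#' @param map a [ConcentrationMap-class].
#' @param library named list of [BandSpectrum-class].
#' @param psfRaman,psfIr [psfModel()]s.
#' @param exc an [excitationConfig()].
#' @param gains contrast gains, see [renderContrast()].
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()].
#' @param noise a [noiseConfig()] (full path only).
#' @param lockIr,lockRaman [lockinConfig()]s; defaults demodulate at
#'   \code{cfg$fIr} and \code{cfg$fStokesMod}.
#' @param path \code{"fast"} or \code{"full"}.
#' @param seed global seed for per-pixel noise.
#' @param outputGain numeric(2), export gains for the IR and Raman channels
#'   (stored in metadata, not applied to the pixel values).
#' @return an [ImagePair-class].
#' @export
scanImage <- function(map, library, psfRaman = psfModel(398),
                      psfIr = psfModel(561), exc = excitationConfig(),
                      gains = c(kSrl = 5e-8, kPt = 0.018),
                      cfg = pulseTrainConfig(), th = thermalConfig(),
                      noise = noiseConfig(), lockIr = NULL,
                      lockRaman = NULL, path = c("fast", "full"),
                      seed = 1L, outputGain = c(ir = 100, raman = 1000)) {
    path <- match.arg(path)
    contrast <- renderContrast(map, library, psfRaman, psfIr, exc, gains)
    ds <- contrast@deltaSrl; dp <- contrast@deltaPt
    d <- dim(ds)
    ir <- matrix(0, d[1], d[2]); raman <- matrix(0, d[1], d[2])
    if (path == "fast") {
        if (noise$rin > 0 || noise$shotScale > 0)
            warning("fast path is noiseless-analytic; noise config ignored")
        a <- .fastChannelAmplitudes(ds, dp, cfg, th)
        ir <- a$ir; raman <- a$raman
    } else {
        if (is.null(lockIr)) lockIr <- lockinConfig(cfg$fIr)
        if (is.null(lockRaman)) lockRaman <- lockinConfig(cfg$fStokesMod)
        for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
            ns <- noise
            ns$seed <- pixelSeed(seed, i, j)
            tr <- synthTrace(ds[i, j], dp[i, j], cfg, th, ns)
            ir[i, j] <- lockin(tr, lockIr)
            raman[i, j] <- lockin(tr, lockRaman)
        }
    }
    new("ImagePair", ir = ir, raman = raman, pixelSize = map@pixelSize,
        meta = list(excitation = exc, gains = as.list(gains),
                    psfRamanFwhm = psfRaman$fwhm, psfIrFwhm = psfIr$fwhm,
                    train = cfg, thermal = th, noise = noise, path = path,
                    seed = seed, outputGain = as.list(outputGain)))
}

#' Quasi-simultaneous two-pass point spectra
#'
#' Emulates spectral acquisition at a fixed pixel: pass one sweeps the
#' mid-IR wavenumber on a 2 cm^-1 grid (fast quantum-cascade-laser tuning)
#' with the Raman detuning fixed; pass two sweeps the Raman detuning on an
#' 8 cm^-1 grid. Each point is demodulated exactly as in [scanImage()].
#' On the noiseless fast path the recovered spectra are proportional to the
#' species' configured band spectra at that pixel.
#'
#' @param map a [ConcentrationMap-class].
#' @param pixel integer c(row, col) of the probed pixel.
#' @param library named list of [BandSpectrum-class].
#' @param psfRaman,psfIr,exc,gains,cfg,th,noise,seed as in [scanImage()].
#' @param irRange,ramanRange sweep ranges (cm^-1); the IR range must lie
#'   within the 915-2335 cm^-1 tuning range.
#' @param irStep,ramanStep grid spacings (cm^-1), defaults 2 and 8.
#' @param path \code{"fast"} (noiseless-analytic, default) or \code{"full"}
#'   (full waveform synthesis at every sweep point).
#' @return a [SpectrumResult-class].
#' @export
sweepSpectrum <- function(map, pixel, library, psfRaman = psfModel(398),
                          psfIr = psfModel(561), exc = excitationConfig(),
                          gains = c(kSrl = 5e-8, kPt = 0.018),
                          cfg = pulseTrainConfig(), th = thermalConfig(),
                          noise = noiseConfig(), irRange = c(915, 2335),
                          ramanRange = c(2800, 3050), irStep = 2,
                          ramanStep = 8, path = c("fast", "full"),
                          seed = 1L) {
    path <- match.arg(path)
    d <- dim(map@grid)
    if (length(pixel) != 2L || any(pixel < 1) || pixel[1] > d[1] ||
        pixel[2] > d[2])
        stop("'pixel' outside the map")
    if (irRange[1] < 915 || irRange[2] > 2335)
        stop("IR sweep range outside the QCL tuning range 915-2335 cm^-1")
    pxNm <- map@pixelSize * 1e3
    kRaman <- gaussianKernel(psfRaman$fwhm, pxNm, psfRaman$truncation)
    kIr <- gaussianKernel(psfIr$fwhm, pxNm, psfIr$truncation)
    convR <- vapply(seq_along(map@species), function(s)
        convolveReflect(map@grid[, , s], kRaman)[pixel[1], pixel[2]],
        numeric(1))
    convI <- vapply(seq_along(map@species), function(s)
        convolveReflect(map@grid[, , s], kIr)[pixel[1], pixel[2]],
        numeric(1))
    irAxis <- seq(irRange[1], irRange[2], by = irStep)
    ramanAxis <- seq(ramanRange[1], ramanRange[2], by = ramanStep)
    oneValue <- function(ds, dp, which, seedOff) {
        if (path == "fast") {
            a <- .fastChannelAmplitudes(ds, dp, cfg, th)
            a[[which]]
        } else {
            ns <- noise
            ns$seed <- pixelSeed(seed, seedOff, if (which == "ir") 1L else 2L)
            tr <- synthTrace(ds, dp, cfg, th, ns)
            lockin(tr, lockinConfig(
                if (which == "ir") cfg$fIr else cfg$fStokesMod))
        }
    }
    # pass 1: IR sweep, Raman detuning fixed
    dsFix <- gains[["kSrl"]] * exc$pPump * exc$pStokes *
        sum(convR * vapply(map@species, function(sp)
            evaluateSpectrum(library[[sp]], exc$ramanWavenumber, "Raman"),
            numeric(1)))
    irValues <- vapply(seq_along(irAxis), function(i) {
        dp <- gains[["kPt"]] * exc$pIr *
            sum(convI * vapply(map@species, function(sp)
                evaluateSpectrum(library[[sp]], irAxis[i], "IR"),
                numeric(1)))
        oneValue(dsFix, dp, "ir", i)
    }, numeric(1))
    # pass 2: Raman sweep, IR wavenumber fixed
    dpFix <- gains[["kPt"]] * exc$pIr *
        sum(convI * vapply(map@species, function(sp)
            evaluateSpectrum(library[[sp]], exc$irWavenumber, "IR"),
            numeric(1)))
    ramanValues <- vapply(seq_along(ramanAxis), function(i) {
        ds <- gains[["kSrl"]] * exc$pPump * exc$pStokes *
            sum(convR * vapply(map@species, function(sp)
                evaluateSpectrum(library[[sp]], ramanAxis[i], "Raman"),
                numeric(1)))
        oneValue(ds, dpFix, "raman", i)
    }, numeric(1))
    new("SpectrumResult", irAxis = irAxis, irValues = irValues,
        ramanAxis = ramanAxis, ramanValues = ramanValues,
        meta = list(pixel = pixel, excitation = exc, path = path))
}
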