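#' Pulse-train configuration
#'
#' Timing of the three excitation/probe pulse trains: the 80-MHz probe
#' repetition rate, the 20-MHz Stokes gating (so each group of
#' \code{fProbe/fStokesMod} probe pulses alternates Raman-on/Raman-off),
#' and the 100-kHz train of 500-ns mid-IR heating pulses. The probe pulse
#' width (2 ps) is far below the detector-limited sample period and is
#' carried as metadata only.
#'
#' @param fProbe probe repetition rate (Hz), default 80 MHz.
#' @param fStokesMod Stokes modulation frequency (Hz), default 20 MHz;
#'   \code{fProbe/fStokesMod} must be an even integer.
#' @param fIr mid-IR repetition rate (Hz), default 100 kHz.
#' @param irPulseWidth mid-IR pulse duration (s), default 500 ns.
#' @param probePulseWidth probe pulse duration (s), metadata only.
#' @param sampleRate detector sampling rate (Hz), default 1.28 GS/s
#'   (16 samples per probe period); must be >= \code{2 fProbe}.
#' @param dwell pixel dwell time (s); should cover several IR periods.
#' @return list with class \code{"PulseTrainConfig"}.
#' @export
pulseTrainConfig <- function(fProbe = 80e6, fStokesMod = 20e6, fIr = 1e5,
                             irPulseWidth = 500e-9, probePulseWidth = 2e-12,
                             sampleRate = 1.28e9, dwell = 100e-6) {
    for (nm in c("fProbe", "fStokesMod", "fIr", "irPulseWidth",
                 "sampleRate", "dwell"))
        assertScalar(get(nm), nm)
    ratio <- fProbe / fStokesMod
    if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) %% 2 != 0)
        stop("fProbe / fStokesMod must be an even integer")
    if (sampleRate < 2 * fProbe)
        stop("sampleRate must be at least 2 * fProbe (aliasing guard)")
    if (irPulseWidth >= 1 / fIr)
        stop("irPulseWidth must be shorter than the IR period")
    structure(list(fProbe = fProbe, fStokesMod = fStokesMod, fIr = fIr,
                   irPulseWidth = irPulseWidth,
                   probePulseWidth = probePulseWidth,
                   sampleRate = sampleRate, dwell = dwell),
              class = "PulseTrainConfig")
}

#' Thermal response configuration
#'
#' Phenomenological single-exponential photothermal response: during each
#' mid-IR pulse the transmission modulation rises toward \code{peakDepth}
#' with time constant \code{tauRise}; after the pulse it relaxes with
#' \code{tauDecay}. The defaults (100 ns rise, 1 us decay) keep harmonics
#' of the 100-kHz fundamental visible up to the few-MHz region, as a thin
#' absorbing film shows; both constants are free parameters of the twin
#' since they are sample- and geometry-dependent.
#'
#' The default rise constant (200 ns) is chosen so the envelope's harmonic
#' comb decays into insignificance above roughly 5 MHz -- matching the
#' observed spectral architecture, where photothermal harmonics extend to
#' about 5 MHz and no envelope content reaches the 20-MHz Raman window
#' (mixing-peak-free operation).
#'
#' @param tauRise heating time constant (s).
#' @param tauDecay relaxation time constant (s).
#' @param peakDepth peak fractional transmission modulation (dimensionless);
#'   usually supplied per pixel from a [ContrastPair-class] (see
#'   [synthTrace()]) and left \code{NA} here.
#' @return list with class \code{"ThermalConfig"}.
#' @seealso [ptPeakFromAverage()] for calibrating the peak depth against a
#'   measured dwell-averaged modulation.
#' @export
thermalConfig <- function(tauRise = 200e-9, tauDecay = 1e-6,
                          peakDepth = NA_real_) {
    assertScalar(tauRise, "tauRise"); assertScalar(tauDecay, "tauDecay")
    structure(list(tauRise = tauRise, tauDecay = tauDecay,
                   peakDepth = peakDepth),
              class = "ThermalConfig")
}

#' Detector noise configuration
#'
#' @param rin relative intensity noise: per-sample Gaussian standard
#'   deviation as a fraction of the sample value (0 disables).
#' @param shotScale photons per sample at unit intensity for the Gaussian
#'   shot-noise approximation (0 disables).
#' @param seed integer seed used for the noise draws.
#' @return list with class \code{"NoiseConfig"}.
#' @export
noiseConfig <- function(rin = 0, shotScale = 0, seed = 1L) {
    assertScalar(rin, "rin", strict = FALSE)
    assertScalar(shotScale, "shotScale", strict = FALSE)
    structure(list(rin = rin, shotScale = shotScale, seed = seed),
              class = "NoiseConfig")
}

# Periodic steady-state envelope parameters: value at the start (mMin) and
# end (mMax) of the IR pulse, from the exponential rise/decay recursion
# fixed point.
.envelopeFixedPoint <- function(cfg, th, peak) {
    tp <- cfg$irPulseWidth
    toff <- 1 / cfg$fIr - tp
    a <- exp(-tp / th$tauRise)
    b <- exp(-toff / th$tauDecay)
    mMax <- peak * (1 - a) / (1 - a * b)
    list(mMin = mMax * b, mMax = mMax, tp = tp, toff = toff)
}

# Envelope evaluated at arbitrary times (s), periodic steady state, first
# IR pulse starting at t = 0.
.envelopeAt <- function(t, cfg, th, peak) {
    if (peak == 0) return(numeric(length(t)) )
    fp <- .envelopeFixedPoint(cfg, th, peak)
    ph <- t %% (1 / cfg$fIr)
    inPulse <- ph < fp$tp
    m <- numeric(length(t))
    m[inPulse] <- peak + (fp$mMin - peak) * exp(-ph[inPulse] / th$tauRise)
    m[!inPulse] <- fp$mMax * exp(-(ph[!inPulse] - fp$tp) / th$tauDecay)
    m
}

#' Photothermal modulation envelope
#'
#' Periodic steady-state transmission-modulation envelope \eqn{m(t)} at the
#' mid-IR repetition rate: exponential rise toward the peak depth during
#' each 500-ns IR pulse, exponential decay afterwards, with
#' \eqn{0 \le m(t) \le} \code{peakDepth} and the first IR pulse starting at
#' \eqn{t = 0}.
#'
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()] with \code{peakDepth} set.
#' @param times optional times (s) at which to evaluate; default is the
#'   full dwell at the configured sample rate.
#' @return numeric vector of modulation values in \code{[0, peakDepth]}.
#' @export
irEnvelope <- function(cfg, th, times = NULL) {
    peak <- th$peakDepth
    if (is.na(peak)) stop("thermalConfig 'peakDepth' must be set")
    if (peak < 0 || peak >= 1)
        stop("'peakDepth' must be in [0, 1)")
    if (cfg$dwell < 1 / cfg$fIr)
        stop("dwell shorter than one IR period")
    if (is.null(times)) {
        n <- round(cfg$dwell * cfg$sampleRate)
        times <- (seq_len(n) - 1) / cfg$sampleRate
    }
    .envelopeAt(times, cfg, th, peak)
}

#' Envelope waveform statistics
#'
#' Dwell-averaged value and 100-kHz fundamental amplitude of the
#' steady-state envelope for a unit peak depth, computed on a fine grid
#' over one IR period. Both scale linearly with the peak depth.
#'
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()] (its \code{peakDepth} is ignored).
#' @param nGrid grid points per IR period.
#' @return list with \code{mean} and \code{fundamental} (amplitude of the
#'   cosine component at \code{fIr}) of the unit-peak envelope.
#' @export
envelopeShape <- function(cfg, th, nGrid = 8192L) {
    t <- (seq_len(nGrid) - 1) / nGrid / cfg$fIr
    m <- .envelopeAt(t, cfg, thermalConfig(th$tauRise, th$tauDecay, 1), 1)
    c1 <- sum(m * exp(-2i * pi * (seq_len(nGrid) - 1) / nGrid)) / nGrid
    list(mean = mean(m), fundamental = 2 * Mod(c1))
}

#' Calibrate envelope peak depth from an average modulation
#'
#' The measurable photothermal quantity at millisecond dwell times is the
#' dwell-averaged fractional probe-power decrease (for example, a
#' 1.8 percent decrease of the Raman channel per milliwatt of average mid-IR
#' power). With a 5 percent IR duty cycle the instantaneous peak modulation
#' is necessarily larger than that average; this helper converts the
#' average into the peak depth the envelope model needs.
#'
#' @param average dwell-averaged fractional modulation (dimensionless).
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()].
#' @return peak depth such that \code{mean(irEnvelope(...)) == average}.
#' @export
ptPeakFromAverage <- function(average, cfg, th) {
    assertScalar(average, "average", strict = FALSE)
    average / envelopeShape(cfg, th)$mean
}

#' Stokes gating sequence
#'
#' Per-probe-pulse binary gate implementing the square-wave Stokes
#' modulation at \code{fStokesMod} with 50 percent duty: with the default
#' 80/20 ratio the repeating pattern over four probe pulses is
#' on, on, off, off; the first pulse is on.
#'
#' @param cfg a [pulseTrainConfig()].
#' @param nPulses number of probe pulses to generate (default: one dwell).
#' @return integer vector of 0/1 gates, length \code{nPulses}.
#' @export
srlGate <- function(cfg, nPulses = NULL) {
    ratio <- round(cfg$fProbe / cfg$fStokesMod)
    if (ratio %% 2 != 0) stop("fProbe / fStokesMod must be an even integer")
    if (is.null(nPulses)) nPulses <- floor(cfg$dwell * cfg$fProbe)
    pattern <- rep(c(1L, 0L), each = ratio / 2)
    rep_len(pattern, nPulses)
}

#' Synthesize the probe-intensity waveform for one pixel dwell
#'
#' Probe pulse \eqn{k}, at \eqn{t_k = k / f_{probe}}, carries energy
#' \deqn{E_k = E_0 (1 - \delta_{SRL}\, g_k)(1 - m(t_k))}
#' where \eqn{g_k} is the Stokes gate and \eqn{m(t)} the photothermal
#' envelope applied multiplicatively to all pulses (the origin of the
#' IR-power-dependent decrease of the demodulated Raman channel). Pulses
#' are rendered as single-sample-wide rectangles of height \eqn{E_k}, so
#' the sum of samples equals \eqn{\sum_k E_k} exactly. Optional relative
#' intensity noise and Gaussian shot noise are applied afterwards and the
#' result clipped at zero.
#'
#' With both modulations zero and noise off the trace is a constant-
#' amplitude 80-MHz pulse train.
#'
#' @param deltaSrl per-pulse SRL fractional loss (0 <= x < 1).
#' @param deltaPt peak photothermal modulation depth (0 <= x < 1). Note
#'   this is the envelope peak; see [ptPeakFromAverage()] for calibration
#'   against a dwell-averaged modulation.
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()] (taus; peak depth comes from
#'   \code{deltaPt}).
#' @param noise a [noiseConfig()].
#' @param E0 pulse energy scale (arbitrary units).
#' @return a [TimeTrace-class].
#' @export
synthTrace <- function(deltaSrl, deltaPt, cfg = pulseTrainConfig(),
                       th = thermalConfig(), noise = noiseConfig(),
                       E0 = 1) {
    assertScalar(deltaSrl, "deltaSrl", strict = FALSE)
    assertScalar(deltaPt, "deltaPt", strict = FALSE)
    if (deltaSrl >= 1 || deltaPt >= 1)
        stop("modulation depths must be < 1")
    if (cfg$sampleRate < 2 * cfg$fProbe)
        stop("sampleRate must be at least 2 * fProbe (aliasing guard)")
    n <- round(cfg$dwell * cfg$sampleRate)
    nPulses <- floor(cfg$dwell * cfg$fProbe)
    tk <- (seq_len(nPulses) - 1) / cfg$fProbe
    gate <- srlGate(cfg, nPulses)
    m <- if (deltaPt > 0)
        .envelopeAt(tk, cfg, thermalConfig(th$tauRise, th$tauDecay, deltaPt),
                    deltaPt)
    else numeric(nPulses)
    Ek <- E0 * (1 - deltaSrl * gate) * (1 - m)
    x <- numeric(n)
    idx <- round(tk * cfg$sampleRate) + 1
    keep <- idx <= n
    x[idx[keep]] <- Ek[keep]
    if (noise$rin > 0 || noise$shotScale > 0) {
        x <- withSeed(noise$seed, {
            y <- x
            if (noise$rin > 0)
                y <- y * (1 + stats::rnorm(n, sd = noise$rin))
            if (noise$shotScale > 0)
                y <- y + sqrt(pmax(y, 0) / noise$shotScale) * stats::rnorm(n)
            y
        })
        x[x < 0] <- 0
    }
    new("TimeTrace", samples = x, sampleRate = cfg$sampleRate,
        meta = list(train = cfg, thermal = th, noise = noise,
                    deltaSrl = deltaSrl, deltaPt = deltaPt, E0 = E0))
}

#' Predicted cross-modulation sideband-to-carrier ratio
#'
#' The product \eqn{(1 - \delta_{SRL} g_k)(1 - m(t))} mixes the 20-MHz
#' Raman-loss carrier with the 100-kHz photothermal envelope and generates
#' sidebands at \eqn{f_{Stokes} \pm f_{IR}}. Their amplitude relative to
#' the carrier is the AM sideband identity
#' \deqn{\mathrm{ratio} = \frac{A_1(m) / 2}{1 - \bar m}}
#' where \eqn{A_1(m)} is the 100-kHz fundamental amplitude of the envelope
#' and \eqn{\bar m} its mean. For a sinusoidal envelope of depth \eqn{d}
#' this reduces to \eqn{d/2}. The predicted level is used to verify that
#' the mixing peaks exist in a noiseless simulation at exactly this (small)
#' level and fall below the noise floor at realistic noise settings.
#'
#' @param deltaSrl per-pulse SRL loss (only its being nonzero matters: the
#'   ratio is taken relative to the SRL carrier).
#' @param deltaPt peak photothermal modulation depth.
#' @param cfg a [pulseTrainConfig()].
#' @param th a [thermalConfig()].
#' @return sideband-to-carrier amplitude ratio (dimensionless).
#' @export
crosstalkDepth <- function(deltaSrl, deltaPt, cfg = pulseTrainConfig(),
                           th = thermalConfig()) {
    if (deltaPt == 0) return(0)
    sh <- envelopeShape(cfg, th)
    (deltaPt * sh$fundamental / 2) / (1 - deltaPt * sh$mean)
}
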