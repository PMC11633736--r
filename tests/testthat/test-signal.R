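test_that("photothermal envelope follows the exponential rise/decay fixed point", {
    cfg <- pulseTrainConfig()
    expect_equal(max(irEnvelope(cfg, thermalConfig(peakDepth = 0))), 0)

    # near-step response: instant rise, negligible decay
    mStep <- irEnvelope(cfg, thermalConfig(1e-12, 1e6, peakDepth = 0.1))
    expect_equal(max(mStep), 0.1, tolerance = 1e-6)
    expect_equal(min(mStep), 0.1, tolerance = 1e-3)

    # closed-form geometric-series fixed point at 5% duty
    th <- thermalConfig(200e-9, 1e-6, peakDepth = 0.1)
    m <- irEnvelope(cfg, th)
    o <- envelopeFixedPointOracle(0.1, 500e-9, 9.5e-6, 200e-9, 1e-6)
    expect_equal(max(m), o$mMax, tolerance = 1e-6)
    expect_equal(min(m), o$mMin, tolerance = 1e-3)
    expect_true(all(m >= 0 & m <= 0.1))

    expect_error(irEnvelope(pulseTrainConfig(dwell = 5e-6),
                            thermalConfig(peakDepth = 0.1)), "IR period")
})

test_that("Stokes gate is a 50%-duty square wave starting on", {
    cfg <- pulseTrainConfig()
    expect_equal(srlGate(cfg, 8), c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L))
    cfg2 <- pulseTrainConfig(fProbe = 80e6, fStokesMod = 40e6)
    expect_equal(srlGate(cfg2, 6), c(1L, 0L, 1L, 0L, 1L, 0L))
    g <- srlGate(cfg)
    expect_lt(abs(mean(g) - 0.5), 1 / length(g) + 1e-12)
    expect_error(pulseTrainConfig(fStokesMod = 30e6), "even integer")
})

test_that("trace synthesis conserves pulse energies and encodes both modulations", {
    cfg <- pulseTrainConfig()
    tr0 <- synthTrace(0, 0, cfg)
    x <- samples(tr0)
    pulses <- x[x > 0]
    expect_equal(length(pulses), floor(cfg$dwell * cfg$fProbe))
    expect_true(all(pulses == pulses[1]))          # constant-amplitude train
    expect_equal(sum(x), length(pulses) * pulses[1])  # energy conservation

    # SRL gating: on/off pulse-energy ratio equals 1 - delta_srl
    trS <- synthTrace(1e-3, 0, cfg)
    Ek <- samples(trS)[samples(trS) > 0]
    gate <- srlGate(cfg, length(Ek))
    expect_equal(mean(Ek[gate == 1]) / mean(Ek[gate == 0]), 0.999,
                 tolerance = 1e-12)

    # photothermal dc drop equals the time-average of the envelope
    th <- thermalConfig()
    pk <- ptPeakFromAverage(0.018, cfg, th)
    trP <- synthTrace(0, pk, cfg, th)
    drop <- 1 - dcLevel(trP) / dcLevel(tr0)
    expect_equal(drop, 0.018, tolerance = 1e-3)

    expect_error(synthTrace(0, 0, pulseTrainConfig(sampleRate = 1.5e8)),
                 "aliasing|fProbe")
})

test_that("noisy traces are bit-reproducible under a fixed seed", {
    cfg <- pulseTrainConfig(dwell = 20e-6)
    nz <- noiseConfig(rin = 5e-3, shotScale = 1e4, seed = 42L)
    a <- synthTrace(0.01, 0.02, cfg, noise = nz)
    b <- synthTrace(0.01, 0.02, cfg, noise = nz)
    expect_identical(samples(a), samples(b))
    c2 <- synthTrace(0.01, 0.02, cfg, noise = noiseConfig(5e-3, 1e4, 43L))
    expect_false(identical(samples(a), samples(c2)))
    expect_true(all(samples(a) >= 0))
})

test_that("cross-modulation sidebands follow the AM identity and the analytic level", {
    cfg <- pulseTrainConfig(dwell = 1e-3)
    th <- thermalConfig()
    expect_equal(crosstalkDepth(0.05, 0, cfg, th), 0)

    # AM identity oracle: hand-built pulse train with a sinusoidal envelope
    d <- 0.04; ds <- 0.05
    np <- floor(cfg$dwell * cfg$fProbe)
    tk <- (seq_len(np) - 1) / cfg$fProbe
    gate <- srlGate(cfg, np)
    Ek <- (1 - ds * gate) * (1 - d * cos(2 * pi * cfg$fIr * tk))
    carrier <- fftAmplitude(Ek, cfg$fStokesMod, cfg$fProbe)
    sb <- (fftAmplitude(Ek, cfg$fStokesMod + cfg$fIr, cfg$fProbe) +
           fftAmplitude(Ek, cfg$fStokesMod - cfg$fIr, cfg$fProbe)) / 2
    expect_equal(sb / carrier, d / 2, tolerance = 0.01)

    # analytic prediction vs FFT of a full synthesized trace within 5%
    tr <- synthTrace(0.05, 0.018, cfg, th)
    x <- samples(tr); fs <- sampleRate(tr)
    carrier2 <- fftAmplitude(x, cfg$fStokesMod, fs)
    sb2 <- (fftAmplitude(x, cfg$fStokesMod + cfg$fIr, fs) +
            fftAmplitude(x, cfg$fStokesMod - cfg$fIr, fs)) / 2
    pred <- crosstalkDepth(0.05, 0.018, cfg, th)
    expect_lt(abs(sb2 / carrier2 - pred) / pred, 0.05)
})

test_that("noiseless spectrum shows the three modulation frequencies as dominant peaks", {
    cfg <- pulseTrainConfig(dwell = 1e-3)
    th <- thermalConfig()
    tr <- synthTrace(0.02, ptPeakFromAverage(0.05, cfg, th), cfg, th)
    ps <- powerSpectrum(tr)
    # a 5-MHz separation groups each carrier with its envelope sidebands;
    # the band is capped at 50 MHz because pulse sampling at 80 MHz mirrors
    # the 20-MHz gating line to 60 MHz with equal amplitude
    pk <- topPeaks(ps, k = 2, minSep = 5e6, fMax = 50e6)
    expect_equal(pk, c(1e5, 20e6))
    at <- function(f) ps$psd[which.min(abs(ps$frequency - f))]
    expect_gt(at(80e6), at(20e6))
    expect_gt(at(80e6), at(1e5))
})
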