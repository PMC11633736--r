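# inspiresim

A digital twin of a single-probe pump-probe IR + Raman (INSPIRE-style)
microscope, written for instrument builders and image analysts who want to
reason about frequency-multiplexed vibrational imaging without hardware:
what the detector waveform looks like, how the two chemical channels are
demodulated from it, how cross-modulation between them scales, and how the
downstream image-analysis recipes (unmixing, ratiometric imaging, droplet
morphometry) behave on specimens with known ground truth.

## The measurement being simulated

A picosecond probe pulse train at repetition rate `f_probe = 80 MHz`
carries two signals at once:

* **Stimulated Raman loss (SRL).** When the pump-Stokes detuning matches a
  Raman-active band, each probe pulse coincident with the Stokes beam loses
  a fraction `delta_SRL` of its energy. The Stokes beam is gated at
  `f_S = 20 MHz` (pattern on, on, off, off across probe pulses), so the SRL
  signal lives at 20 MHz.
* **Mid-IR photothermal modulation (MIP).** 500-ns mid-IR pulses at
  `f_IR = 100 kHz` heat the focal volume when the IR wavenumber matches an
  IR-active band; the resulting transmission change `m(t)` modulates the
  whole train as a slow envelope, so the IR signal lives at 100 kHz.

The detected intensity of probe pulse *k* at time `t_k = k / f_probe` is

    E_k = E0 * (1 - delta_SRL * g_k) * (1 - m(t_k))

with `g_k` the 20-MHz gate and `m(t)` an exponential rise/decay envelope
(rise `tau_r` during each IR pulse, decay `tau_d` after it). Because
100 kHz, 20 MHz and 80 MHz occupy disjoint spectral windows, both channels
are recovered simultaneously from one waveform by software lock-in
demodulation (quadrature mixing, cascaded single-pole low-pass, magnitude
`2 * sqrt(I^2 + Q^2)` calibrated so a unit cosine returns 1).

The optical forward model maps per-species concentration maps `C_s` through
channel-specific Gaussian point-spread functions and band spectra
`S_s(nu)` (Lorentzian lines):

    delta_SRL = k_srl * P_pump * P_Stokes * sum_s (C_s * PSF_R) * S_s^Raman(nu_R)
    delta_PT  = k_pt  * P_IR             * sum_s (C_s * PSF_IR) * S_s^IR(nu_IR)

Downstream analysis implements per-pixel non-negative least-squares
unmixing, Pearson correlation as a specificity score, the
background-subtract / normalize / add-one / divide ratiometric recipe,
droplet extraction (bilinear interpolation to 0.1 um, Otsu threshold,
8-connected components, circularity filter 0.8-1.0), pooled-variance t and
F tests, and bead-based resolution measurement (Gaussian profile fit plus
deconvolution of the bead size).

## Worked example

Image a 500-nm PMMA bead at the IR 1730 cm^-1 carbonyl band and the Raman
2957 cm^-1 CH3 band, then measure the Raman channel's resolution:

```r
library(inspiresim)

bead  <- makeBeadMap(0.5, pixelSize = 0.05, field = 4)
image <- scanImage(bead, presetLibrary("pmma"),
                   exc = excitationConfig(1730, 2957, pIr = 1))
fw <- fitProfileFwhm(ramanImage(image), "x", pixelSize = 0.05)
fw                     # 482.8  (nm, Gaussian-fit profile width)
deconvolveBead(fw, 500)  # 392.9  (nm, bead size deconvolved)

sp <- sweepSpectrum(bead, c(41, 41), presetLibrary("pmma"),
                    exc = excitationConfig(1730, 2957),
                    irRange = c(1600, 1800), ramanRange = c(2800, 3040))
sp@irAxis[which.max(sp@irValues)]        # 1730  (cm^-1, IR sweep peak)
sp@ramanAxis[which.max(sp@ramanValues)]  # 2960  (cm^-1, 8 cm^-1 grid)
```

The measured 483-nm profile is the 398-nm channel PSF broadened by the
500-nm bead; deconvolution recovers the configured resolution to about 1%.
The two-pass sweep reproduces the configured PMMA band spectrum at the
bead, peaking at the carbonyl band (IR) and at the CH3 stretch (Raman,
within its 8 cm^-1 grid).

Droplet morphometry against known ground truth:

```r
fld <- makeDropletField(50, circularFraction = 0.8, seed = 3)
tab <- extractDroplets(concGrid(fld)[, , 1], pixelSize(fld))
nrow(tab)   # 40: every circular object kept, all 10 elongated rejected
st <- dropletStats(tab, transform(tab, equiv_diameter_um = 1.15 * equiv_diameter_um))
st$tStars   # "***"  (t = -3.72, p = 3.7e-4 for a 15% size shift)
```

A command-line interface over the same functions is provided in
`inst/scripts/inspire.R` (`make-phantom`, `simulate-trace`,
`simulate-image`, `demod`, `psd`, `sweep`, `unmix`, `ratio`, `droplets`,
`stats`, `resolution`), driven by YAML run configurations; every run
writes a provenance log with the configuration hash and seed.

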