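---
title: "A digital twin of single-probe IR + Raman microscopy: models, choices, limits"
author: "inspiresim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A digital twin of single-probe IR + Raman microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(inspiresim)
```

# The measurement model

Single-probe cross-modality vibrational imaging exploits a separation of
time scales. Stimulated Raman loss (SRL) is an ultrafast, per-pulse effect:
a probe pulse overlapped with a gated Stokes pulse loses the fraction
`delta_SRL` of its energy whenever the pump-Stokes detuning matches a
Raman-active vibration. Mid-IR photothermal contrast is slow: a 500-ns IR
pulse deposits heat when the IR wavenumber matches an IR-active band, and
the resulting change of focal transmission relaxes over microseconds. One
probe pulse train therefore carries both: pulse-to-pulse gating encodes
SRL at the 20-MHz Stokes modulation frequency, while the train as a whole
acts as a quasi-continuous probe of the 100-kHz photothermal envelope.

The twin models the detected energy of probe pulse $k$ at
$t_k = k/f_{probe}$ as

$$E_k = E_0\,\bigl(1 - \delta_{SRL}\, g_k\bigr)\,\bigl(1 - m(t_k)\bigr)$$

with $g_k \in \{0,1\}$ the 50%-duty Stokes gate (pattern on-on-off-off at
the default 80/20 MHz ratio, first pulse on) and $m(t)$ the periodic
photothermal envelope. The multiplicative form is deliberate: it is what
couples the two channels, producing the measurable decrease of the
demodulated SRL channel with increasing IR power and the mixing sidebands
at $f_S \pm f_{IR}$.

Assumptions worth keeping in mind:

* **Small-signal regime.** Both modulation depths are treated as
  perturbations of a fixed pulse energy; contrast maps above 0.2 trigger a
  validity warning. No pump depletion, no thermal modification of Raman
  cross sections.
* **Ideal gating.** The Stokes electro-optic modulator is a perfect square
  wave; there is no pulse-to-pulse jitter and no detector impulse
  response. Probe pulses render as single-sample rectangles carrying the
  pulse energy (the physical 2-ps width is metadata; at detector-limited
  sample rates only the energy matters).
* **Phenomenological thermal response.** $m(t)$ rises as
  $1 - e^{-t/\tau_r}$ during each IR pulse and decays as $e^{-t/\tau_d}$
  afterwards, evaluated in its periodic steady state from $t = 0$ (the
  geometric-series fixed point of the rise/decay recursion). There is no
  heat-diffusion PDE; thermal blur is absorbed into the IR channel's
  point-spread function.

# Parameters, defaults, and why

| parameter | default | rationale |
|---|---|---|
| `fProbe` | 80 MHz | probe repetition rate |
| `fStokesMod` | 20 MHz | Stokes gating; `fProbe/fStokesMod` must be an even integer |
| `fIr`, `irPulseWidth` | 100 kHz, 500 ns | mid-IR excitation (5% duty) |
| `sampleRate` | 1.28 GS/s | 16 samples per probe period; resolves the 80-MHz line with margin |
| `dwell` | 100 us | 10 IR periods per pixel; short enough to keep full-waveform scans tractable |
| `tauDecay` | 1 us | sustains envelope harmonics into the MHz region |
| `tauRise` | 200 ns | see below |
| PSF FWHM (Raman / IR) | 398 / 561 nm | the two channels' deconvolved lateral resolutions; the pump-Stokes product focus and thermal-diffusion blur are absorbed into the single configured width per channel |
| `kPt` | 0.018 per mW | a 1.8% fractional transmission decrease per milliwatt of average mid-IR power at unit concentration on a unit-amplitude band |
| lock-in `tau`, `order` | dwell/10, 4 | cascaded single-pole stages; hardware filter settings are not published for this instrument class |

Neither thermal time constant is a published quantity, so both are free
configuration parameters. The rise constant's default (200 ns) was chosen
against the instrument's *reported spectral architecture*: photothermal
harmonics should persist to roughly 5 MHz and no envelope content should
reach the 20-MHz window (mixing-peak-free operation). A substantially
faster rise (e.g. 100 ns) leaves envelope harmonics at 20 MHz that
coherently contaminate the SRL carrier — measurably biasing the
IR-power-dependence of the demodulated Raman channel — which contradicts
those observations.

**Peak versus average depth.** The printed photothermal figure (1.8% per
mW) is a dwell-averaged quantity: at millisecond dwell times the lock-in
sees the time average $\bar m$, not the instantaneous peak. With a 5% IR
duty cycle the peak depth exceeds the average by the inverse of the
envelope's duty-shape factor (about 7x at the defaults).
`ptPeakFromAverage()` performs this calibration explicitly; configuring
the twin with "1.8% per mW" therefore means the *measured* channel
decrease is 1.8% per mW, which is what the regression in the acceptance
chain recovers.

# What the phantoms emulate — and what they do not

* `makeBeadMap()` renders the projected chord thickness of a solid sphere
  ($\sqrt{1-(r/R)^2}$, pixel-center sampling on an odd grid so one pixel
  sits exactly at the bead center). This is the correct thin-sample
  contrast profile for both channels; it is *not* a flat disk.
* `makeMixtureMap()` places non-overlapping circular grains assigned
  cyclically to three species, so the amount per species is a 1:1:1
  mixture. Grain centers snap to pixel centers: every same-sized grain
  covers an identical pixel pattern and the per-species totals are equal
  *exactly*, not just in expectation.
* `makeDropletField()` renders disks plus elongated ellipses (aspect
  ratio >= 3, area-preserving) with per-object intensities and returns
  the exact ground-truth table, so extraction recall is scored against
  construction. Placement forbids touching objects; over-dense requests
  error rather than silently merge.

None of the phantoms include refractive-index contrast, scattering,
3-D sectioning, or spatially correlated background — so green tests say
the *chain* is faithful, not that segmentation would perform equally on
real tissue, where background structure and overlapping organelles
dominate the difficulty.

# Numerical choices in the demodulation chain

* **AC coupling.** The trace mean is removed before quadrature mixing,
  emulating the ac-filtered detection path. Without it, the large dc of a
  pulse train mixes to a full-scale ripple at $f_{ref}$ whose filter
  settling transient corrupts the average at the percent level.
* **Cyclic warm-up.** The cascaded filter is warmed on a cyclic prefix of
  the mixed signal (treating the dwell as one period) before the real
  pass, and a settling interval of five time constants is still
  discarded. A fourth-order cascade left to settle from rest retains a
  measurable transient even after $5\tau$; warm-starting removes it
  without lengthening the dwell.
* **Magnitude convention.** $2\sqrt{I^2+Q^2}$, so a pure cosine of
  amplitude $A$ at the reference returns $A$ (component amplitude, not
  RMS).
* **Welch PSD.** Hann window, 50% overlap, one-sided density scaling that
  integrates to the mean square. Segments default to 0.2 ms so bins are
  exactly 5 kHz and the 100-kHz comb falls on bins. Each segment is
  mean-detrended by default (the standard choice, and again the
  ac-coupled view); Parseval checks use `detrend = "none"`.
* **Fast path.** The virtual scan defaults to analytic demodulated
  amplitudes obtained by projecting the pulse-energy sequence onto the
  two references: the IR channel is $(E_0/16)\,(1-\delta_{SRL}/2)\,A_1(m)$
  with $A_1$ the envelope's 100-kHz fundamental amplitude, the Raman
  channel $(E_0/16)\,\delta_{SRL}\,(\sqrt2/2)\,(1-\bar m)$. The full
  waveform path verifies these within 1% at realistic depths and is used
  whenever noise is requested.
* **One alias to know about.** Pulse sampling at 80 MHz mirrors the
  20-MHz gating line to 60 MHz with equal amplitude (it is the lower
  sideband of the 80-MHz carrier). Peak bookkeeping in the tests
  therefore restricts the SRL-carrier search to the 5-50 MHz band.

# Cross-modulation sidebands

The product $(1-\delta_{SRL}g_k)(1-m)$ generates sidebands at
$f_S \pm f_{IR}$ with carrier-relative amplitude
$\tfrac{1}{2}A_1(m)/(1-\bar m)$ — the AM sideband identity ($d/2$ for a
sinusoidal envelope of depth $d$). The twin verifies this closed form
against the FFT of a noiseless synthetic trace. Whether the sidebands are
*visible* depends on depth and noise: at a 1.8% peak depth and 0.3%
per-sample relative intensity noise they fall below the Welch noise floor,
consistent with mixing-peak-free spectra; at several milliwatts of IR
power a noiseless simulation resolves them at exactly the predicted
level. The prediction isolates the multiplicative mixing term; at very
small SRL depths the envelope's own high harmonics add a floor to the
measured sideband.

# Droplet morphometry: perimeter estimation

The extraction recipe (bilinear interpolation to 0.1 um, Otsu threshold,
8-connected components, circularity $4\pi A/P^2$ in 0.8-1.0, size
threshold at the resolution limit) is sensitive to how $P$ is estimated,
because micrometer droplets are only ~5 interpolated pixels in radius. A
Cauchy-Crofton crossing-count estimate on the binary mask — the
conventional shorthand — fluctuates strongly at that scale (binarization
leaves single-pixel nubs at the axis extremes of a bilinear level set),
misclassifying a third of true disks. The default perimeter is therefore
the sub-pixel marching-squares isoline length at the threshold level
(`grDevices::contourLines`), which is stable: rendered disks score
0.85-1.0 and aspect-3.5 ellipses 0.5-0.8, cleanly split by the 0.8 gate.
Crofton remains available via `perimeter = "crofton"`. Circularity is
clipped at 1.05 to absorb residual discretization overshoot; centroid,
area, equivalent diameter and mean intensity are measured on the
interpolated image. Component labelling is 8-connected (diagonal contact
joins), and an independent flood-fill oracle in the test suite checks the
segmentation on small images.

# Bead deconvolution

Measuring resolution from a bead image conventionally subtracts the bead
in quadrature, treating it as a Gaussian of FWHM equal to its diameter.
For a solid sphere that convention is biased: the projected profile
$\sqrt{1-(r/R)^2}$ has an effective Gaussian width well below the
diameter, and in the 2-D imaging geometry the central line profile of the
blurred bead is narrower still, so $\sqrt{F_{meas}^2 - D^2}$
under-recovers the point-spread function severely. The default
`beadModel = "projection"` therefore inverts the actual measurement chain
numerically: render the projection, blur with a trial Gaussian,
Gaussian-fit the central profile, and solve for the trial width that
reproduces the measurement (`uniroot`, 0.5-nm tolerance). The plain
quadrature remains available as `beadModel = "gaussian"` and satisfies
its algebraic identity. If the measurement does not exceed the bare bead
profile, both modes return 0 with a warning rather than an imaginary
width.

Degenerate inputs across the analysis module follow one rule: impossible
measurements error with diagnostics (flat profiles, multi-peak profiles,
constant images in correlation, all-background images in the ratiometric
recipe, rank-deficient unmixing references), while legitimately empty
results (no components found) return empty tables.

# Problem sizes

The test suite and the acceptance script run at desk scale by choice:
1-2 ms waveforms at 1.28 GS/s for spectral checks, 100-us dwells for
per-pixel demodulation, 81 x 81-pixel bead fields at 50-nm pixels for the
resolution round trip, 100-pixel-wide mixture and droplet fields, and
hundreds of replicates for the t-test power check. These sizes keep every
quantity's estimation error an order of magnitude below its test
tolerance; scaling any of them up changes run time, not conclusions.

# Known limitations

* No heat-diffusion physics: thermal blur and decay are phenomenological,
  so absolute photothermal amplitudes are only as good as the configured
  `kPt` and taus.
* No epi/forward collection geometry differences, no detector transfer
  function, no 1/f noise, no laser jitter.
* Spectral sweeps are quasi-simultaneous two-pass by construction; the
  twin does not model drift between passes.
* The sign of the photothermal transmission change is a convention
  (decrease at the detector, matching the observed SRL-channel decrease
  under IR); magnitude demodulation discards it anyway.
* Preset band tables carry positions from standard assignments but
  relative amplitudes are configuration choices, not literature values;
  the mapping of mixture compounds to exclusive bands is configurable and
  should not be treated as ground truth.
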