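Package: inspiresim
Title: Digital Twin of a Single-Probe Pump-Probe IR and Raman (INSPIRE)
    Microscope
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates frequency-multiplexed single-probe detection of
    mid-infrared photothermal and stimulated Raman loss contrast, as used in
    INSPIRE (in situ pump-probe IR and Raman excitation) microscopy. The
    package generates synthetic specimen phantoms with Lorentzian vibrational
    band spectra, renders per-pixel photothermal and Raman-loss modulation
    depths through channel-specific Gaussian point-spread functions,
    synthesizes the 80-MHz probe pulse-train waveform carrying 20-MHz-gated
    Raman-loss dips under a 100-kHz photothermal envelope, demodulates both
    channels by software lock-in, and assembles images and quasi-simultaneous
    spectra through a virtual scan. Downstream analysis implements power
    normalization, non-negative least-squares spectral unmixing, Pearson
    specificity scores, ratiometric imaging, droplet morphometry with
    circularity filtering, two-sample droplet statistics, and bead-based
    resolution measurement by profile fitting and deconvolution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    pracma,
    minpack.lm,
    EBImage,
    rlang
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
biocViews: Software, Spectroscopy, CellBiology, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
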