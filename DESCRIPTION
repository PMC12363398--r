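Package: auscultQC
Title: Distance-Correlation Quality Evaluation for Auscultation Sensors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluates digital stethoscope sensors recorded on an acoustic
    phantom in the presence of ambient noise. Provides signal-fidelity and
    noise-leakage statistics based on the empirical distance correlation
    (time-domain and Fourier amplitude-spectrum variants), broadband and
    Bark-critical-band windowed quality scores, a spectral signal-to-noise
    ratio, an exponential fidelity-leakage curve fit, material/sensor
    ranking with Pareto analysis, and a characteristic acoustic impedance
    calculator from through-transmission time shifts. A seedable sound-booth
    simulator generates phantom/noise/recording triplets so the entire
    pipeline is testable without laboratory recordings. Includes WAV and
    CSV/JSON input-output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
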