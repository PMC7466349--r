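Package: arsqnmr
Title: Quantification of Total 5-Alkylresorcinols in Cereal Products by 1H qNMR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, processing and internal-standard quantification of
    1H NMR spectra for measuring total 5-alkylresorcinols (ARS) in flour,
    grain and baked products. Provides a Lorentzian spin simulator emulating
    DMSO-d6 flour extracts (T1 saturation, T2 decay, scan-accumulated noise,
    per-cycle extraction efficiency), a 1D processing chain (exponential
    apodization, zero filling, Fourier transform, automatic and manual phase
    correction, polynomial baseline correction, ppm calibration),
    syringaldehyde internal-standard quantification with detection calls
    against S/N-based LOD/LOQ thresholds, and method-validation statistics
    (recovery by extraction cycle, intraday/interday precision,
    relaxation-delay sufficiency). Reads and writes 1D JCAMP-DX.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
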