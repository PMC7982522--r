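Package: phonosim
Title: Prescribed-Motion Phonation Simulation and Voice-Quality Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of human phonation with prescribed vocal-fold
    motion. Builds parametric glottal-closure geometries (five closure types,
    from full closure to a rectangular full-length gap), modifies a baseline
    glottal area waveform for each closure type, imposes a convergent-divergent
    mucosal-wave duct-angle schedule with optional left-right amplitude
    asymmetry, drives a quasi-steady orifice flow model, synthesizes radiated
    sound through a source-filter /a/ vocal tract, and computes aerodynamic and
    acoustic voice-quality measures: mean flow, glottal resistance, net
    aerodynamic energy transfer, amplitude spectral density, sound pressure
    level, vocal efficiency, cepstral peak prominence, formants, and glottal
    quotients.
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
    optparse,
    withr
Config/testthat/edition: 3
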