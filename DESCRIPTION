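Package: melflim
Title: Multiphoton FLIM Analysis of Melanin Autofluorescence
Version: 0.1.0
Authors@R:
    person("melflim", "developers", email = "melflim@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of time-correlated single photon counting
    (TCSPC) fluorescence lifetime imaging (FLIM) data for melanin
    autofluorescence studies. Provides a synthetic TCSPC image generator with
    bi-exponential melanin decay presets, per-pixel bi-exponential
    reconvolution fitting by Poisson maximum likelihood with spatial/temporal
    binning and chi-squared quality control, fit-free phasor analysis with
    reference-fluorophore calibration, phase and modulation lifetimes,
    two-species phasor unmixing, a phasor-distance fraction of UVA-modified
    melanin (fUVA-Mel), region-of-interest summaries with Student t-tests and
    Cohen's d effect sizes, multi-page TIFF input/output, and an end-to-end
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
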