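Package: spicpms
Title: Single-Particle ICP-MS Data Reduction and Measurement Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data reduction for single-particle inductively coupled plasma
    mass spectrometry (spICP-MS) of nanoparticle dispersions: particle event
    detection by an iterative mean + n*sigma threshold, transport-efficiency
    calibration by the particle frequency method, ionic mass calibration,
    conversion of pulse intensities to particle masses and equivalent
    spherical diameters, size-distribution summaries, and number and mass
    concentrations with dilution-series quality control. Includes a
    measurement-uncertainty framework (one-way ANOVA precision components,
    bias uncertainty, combined and expanded uncertainty under routine
    conditions, and quadrature decomposition into sample-preparation and
    analysis contributions) and a synthetic-trace generator with presets
    emulating colloidal silver dispersions, silver food additives (E174),
    and E174-containing confectionery, so the whole chain can be verified
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
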