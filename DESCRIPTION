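Package: megsource
Title: Source-Space Oscillatory Analysis of MEG Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for source-space analysis of
    magnetoencephalography (MEG) recordings: spherical-conductor forward
    modelling on a regular source lattice, vectorised linearly-constrained
    minimum-variance (LCMV) beamforming with noise-normalised power maps
    (Neural Activity Index), permutation maximum-statistic whole-brain
    contrasts, Stockwell-transform time-frequency analysis of virtual
    electrodes, and condition contrasts on time-frequency tiles with
    dual significance criteria and Monte-Carlo cluster-extent correction.
    Includes a synthetic-data generator that injects oscillatory dipole
    sources with known ground truth, for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
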