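Package: toxprint
Title: Toxin Fingerprinting from Intact-Cell MALDI-TOF Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for differentiating toxic effects in
    cell-based ecotoxicological test systems from intact-cell MALDI-TOF mass
    spectra. Covers spectrum simulation with ground truth, smoothing, baseline
    estimation, internal mass recalibration in the square-root-mass domain,
    S/N- and abundance-thresholded peak detection, cross-replicate peak
    matching into consensus tables, control-normalized differential marker
    statistics (Grubbs screening, paired t tests), PCA fingerprints of
    relative-change profiles, and four-parameter logistic dose-response
    (EC50) fitting with outlier detection and Dunnett many-to-one testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    mvtnorm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    mzR,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
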