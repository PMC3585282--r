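Package: ecisbarrier
Title: Barrier Parameter Estimation for Electric Cell-Substrate
    Impedance Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for electric cell-substrate impedance
    sensing (ECIS) of endothelial monolayers. Converts frequency-resolved
    complex impedance spectra of cell-covered electrodes, measured
    relative to a cell-free reference electrode, into the three
    microscopic barrier constants of the Lo-Ferrier-Giaever model: the
    cell-substrate constriction parameter alpha, the junctional barrier
    resistance Rb and the membrane capacitance Cm. Includes
    single-frequency timecourse utilities, replicate-aware statistics
    (one-way ANOVA, paired and unpaired t-tests), relative qPCR
    quantification (delta-delta-Ct), thresholded two-channel
    colocalization of junction and cytoskeleton images, and a synthetic
    data generator (constant-phase-element reference electrodes,
    scenario presets, Voronoi junction images) so every stage can be
    exercised and validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
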