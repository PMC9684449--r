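Package: tdcsim
Title: Transcranial Direct Current Stimulation Electric-Field Modeling on
    Synthetic Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static volume-conduction modeling of transcranial direct
    current stimulation (tDCS) on synthetic multi-compartment head phantoms.
    Generates populations of nested skin/skull/CSF/grey-matter/white-matter
    phantoms, places 10-10 EEG coordinates by the proportional nested-arc
    construction, builds conventional and surround electrode montages
    (bilateral M1, M1-SO, 4x1 high-definition, left-right and
    anterior-posterior pad surround families), solves the conduction equation
    with a preconditioned conjugate-gradient finite-volume solver, validates
    against an analytic multi-shell sphere series solution, computes on-target
    and whole-brain electric-field outcome measures (ROI mean, 99th-percentile
    mean, focality volume, peak location), and runs within-subject
    repeated-measures comparisons (Greenhouse-Geisser corrected ANOVA, Tukey
    post-hoc tests, intraclass correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
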