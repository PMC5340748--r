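Package: lvssa
Title: Statistical Shape and Motion Analysis of the Left Ventricle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end framework for three-dimensional left-ventricular
    shape and motion analysis from cardiac magnetic resonance data. Combines a
    single high-resolution whole-heart volume with a short-axis cine stack by
    propagating cine-derived motion through non-rigid (demons) registration,
    builds per-subject anatomical models (template mesh plus momenta attached
    to a control-point grid, under a currents surface metric), co-aligns
    subjects by volume scaling and generalized Procrustes analysis, and runs
    principal component analysis separately on shape (end-diastole and
    end-systole) and on motion decoupled from shape via a population
    SuperTemplate. Ships a synthetic left-ventricle cohort generator with
    known ground truth so the whole pipeline is testable without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    Matrix,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
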