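Package: asdcad
Title: Personalized Autism Diagnosis from Resting-State fMRI Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for autism spectrum disorder
    built on resting-state functional MRI. Decomposes 4D BOLD volumes into
    spatial networks and time courses with group probabilistic independent
    component analysis and dual regression, matches networks to a 34-area
    functional atlas by spatial correlation, extracts power-spectral-density
    features per area, scores each area's autism-class membership with a
    per-area sparse autoencoder and a probabilistic RBF support vector
    machine, fuses area scores into a global diagnosis, and evaluates with
    cross-validation, label-permutation testing and prevalence-adjusted
    predictive values. Includes a seeded synthetic BOLD phantom generator
    with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
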