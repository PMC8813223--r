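Package: orthoarc
Title: Automated Classification, Archiving and Monitoring of Orthodontic
    Image Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for sorting the standard 14-image
    orthodontic record (six extraoral photographs, six intraoral
    photographs, two radiographs) into its categories and auditing each
    patient's case for duplicate or missing images. Radiographs are
    recognised by their single-channel encoding and routed through an
    aspect-ratio rule; colour photographs pass through a compact residual
    convolutional network that emits a 96-dimensional identity ('DeepID')
    embedding, which a joint Bayesian verification model scores against
    per-category gallery means to produce the final label. Postprocessing
    mirror-flips occlusal photographs taken through an intraoral mirror,
    reports per-patient integrity findings, and writes an archiving table
    with one hyperlinked row per image for human review. A seeded
    synthetic-cohort generator reproduces the cohort structure the
    pipeline assumes so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    pROC,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
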