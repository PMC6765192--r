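Package: zfnvu
Title: Neurovascular-Unit Phenotyping of Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for larval zebrafish neurovascular-unit
    phenotyping. Computes light/dark preference, speed-class time budgets and
    geometric locomotion features (minimum enclosing ellipse eccentricity,
    mean point distance to ellipse centre, mean point distance to well centre)
    from tracked swim trajectories; detects spontaneous calcium transients in
    dF/F0 fluorescence traces; quantifies vessel-normalised fluorescence
    intensity and mural-nuclei counts in two-channel 3-D image stacks; and
    runs the study's two-factor group comparisons (Shapiro-Wilk gate, two-way
    ANOVA, Sidak-adjusted pairwise tests). Ships a synthetic-data generator
    with known ground truth so every stage is testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    readr,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    car,
    emmeans,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
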