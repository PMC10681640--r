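Package: iimkit
Title: Bispectral MR Intensity Normalization and Image-Intensity-Metric
    Trajectory Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-quantitative analysis of paired T1-weighted and FLAIR MR
    images. Normalizes the arbitrary scanner intensity scale by affine
    registration of each session's bivariate T1w/FLAIR intensity histogram to
    a normative reference, extracts regional mean and standard deviation
    intensity metrics over a grey-matter parcellation, fits linear and
    quadratic mixed-effects trajectory models of these metrics against
    estimated years to symptom onset (EYO) and mutation-carrier status with
    Benjamini-Hochberg false-discovery-rate control, and estimates
    atrophy-adjusted partial correlations between intensity metrics and
    amyloid/tau PET uptake. Includes a seeded synthetic-data layer (cohorts,
    image phantoms, morphometry, PET tables) so the full pipeline is testable
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
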