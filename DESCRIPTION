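Package: tmetyper
Title: Tumor-Microenvironment Subtype Classification from Bulk Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bulk tumor expression profiles into four
    tumor-microenvironment (TME) subtypes -- Angiogenic (A), Immune Active
    (IA), Immune Desert (ID) and Immune Suppressed (IS) -- with a shallow
    multilayer perceptron (two tanh hidden neurons, softmax output,
    L-BFGS training). Includes a synthetic cohort simulator with a two-axis
    latent structure and mechanism-of-action linked response rates,
    cross-dataset feature-transferability filtering for gene panels,
    frozen-reference quantile normalization so new cohorts map onto the
    training distribution, mechanism-of-action biomarker calling (B+/B-),
    predictive-biomarker evaluation against RECIST response including a
    prior-probability baseline null model, and latent-space visualization
    of the hidden-layer activations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
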