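Package: growthsens
Title: Sensitivity Analysis for Latent Growth Models with Missing Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assesses how conclusions about change over time in short
    longitudinal panels depend on the assumed missing-data mechanism.
    Fits the linear latent growth model under listwise deletion,
    full-information maximum likelihood (with and without saturated-correlates
    auxiliary variables), joint multivariate-normal multiple imputation with
    Rubin's-rules pooling (with and without auxiliaries in the imputation
    model), and pattern-mixture models for dropout (a two-group
    shared-variance model and identifying-restriction models over dropout
    subgroups). Includes Little's MCAR test, dropout-group comparisons,
    auxiliary-variable screening, a synthetic-data generator with
    controllable MCAR/MAR/MNAR dropout, and a classifier that applies
    reporting guidelines to the cross-technique comparison.
License: MIT
Encoding: UTF-8
Imports: MASS, stats, tools, utils
Suggests: lme4, testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
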