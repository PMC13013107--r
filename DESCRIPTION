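Package: pamet
Title: Phenotype-Aligned Metabolomics for Event-Anchored Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns longitudinal metabolomics samples to individual
    clinical-event times instead of fixed calendar days, stratifies
    pre-event samples into temporal windows, selects covariate-matched
    control samples, and runs a multi-method differential screen
    (Student, Welch, Mann-Whitney, Brown-Forsythe trigger) with
    Benjamini-Hochberg control, log-ratio features, and clinical
    evaluation of candidate predictors (standardized logistic models,
    bootstrap and DeLong ROC comparison, Spearman outcome correlations,
    Monte Carlo single-sample sensitivity). Ships a synthetic-cohort
    generator with event-locked spike-in effects so the whole pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
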