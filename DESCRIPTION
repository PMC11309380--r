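Package: metaboost
Title: Multi-Analyte Pattern Mining for Metabolite Concentration Class
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting a fruit secondary metabolite's
    concentration class (high or low) from an ensemble of per-image binary
    classifiers. Implements mean-threshold class labeling, random
    80:10:10 shuffle cross-validation, exhaustive enumeration of
    class-assignment patterns over ten fruit and leaf metabolite models,
    selection of patterns with complete specificity for the fruit
    azadirachtin class, sensitivity-versus-support curves, boosted class
    prediction with a Pick / Do-not-Pick decision rule, a synthetic-data
    generator (beta marginals under a Gaussian copula plus configurable
    surrogate predictors with plantable deterministic rules), and the
    aspect-fit letterbox and non-max-suppression utilities used by the
    companion mobile detector pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
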