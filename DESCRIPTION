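Package: swimmetab
Title: Metabolic Phenotyping of Exercise Intensity Domains in Swimmers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for acute-exercise metabolic phenotyping of
    paired pre/post plasma metabolite profiles collected across the moderate,
    heavy, and severe exercise intensity domains. Provides QC feature
    filtering with pooled-QC relative standard deviation and intensity rules,
    iterative random-forest imputation, per-participant log2 fold changes,
    orthogonal partial least squares discriminant analysis (OPLS-DA) with
    stratified cross-validation, permutation testing, variable importance in
    projection (VIP) scores and third-class projection, Cliff's delta
    eruption tables, per-metabolite linear mixed models with
    trial-heteroscedastic residual variance and cluster-bootstrap confidence
    intervals, critical swimming speed analytics for the 12 x 25 m test
    (peak speed, critical speed, drop-off, exponential speed-time model,
    D-prime), and a synthetic cohort generator that emulates the study
    design for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    ranger,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
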