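Package: mrmediate
Title: Two-Sample Mendelian Randomization with Mediation Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete analysis chain for two-sample Mendelian randomization
    (MR) from GWAS summary statistics: instrument selection (p-value
    thresholding, greedy LD clumping, R-squared/F instrument-strength
    scoring), allele harmonization across exposure and outcome studies,
    univariable causal estimators (Wald ratio, fixed- and random-effects
    inverse-variance weighting, MR-Egger, weighted median, weighted mode),
    sensitivity diagnostics (Cochran's Q heterogeneity, Egger-intercept
    pleiotropy test, leave-one-out, MR-PRESSO outlier detection, funnel-plot
    coordinates), multivariable MR for direct effects, and a two-step
    mediation decomposition with Propagation-of-Error and Sobel inference
    including mediated proportions. Includes a seeded generator of synthetic
    GWAS summary statistics with known causal, pleiotropic, and mediation
    structure, plus a config-driven pipeline and Benjamini-Hochberg FDR
    reporting across exposure panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
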