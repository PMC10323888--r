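Package: stromasig
Title: Anchor-Gene Stromal Signatures and Survival Stratification for
    Tumor Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives anchor-gene correlation signatures from multi-cohort
    gene expression data and evaluates their clinical impact. Implements a
    per-cohort Pearson correlation screen against an anchor gene with
    Benjamini-Hochberg adjustment and cross-cohort intersection, per-sample
    signature scoring (mean z-score and marker-set population scores),
    survival stratification by maximally selected log-rank statistics
    (Hothorn-Lausen) and quantile cutoffs, Kaplan-Meier and log-rank
    analysis, Cox modelling with a univariate-to-multivariable entry rule,
    nearest-centroid molecular subtype transfer, two-group differential
    expression with empirical-Bayes variance moderation, and an
    intersection-based invasiveness signature. Ships a synthetic
    multi-cohort generator with a latent stromal factor and proportional
    hazards survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
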