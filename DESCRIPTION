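Package: volaging
Title: Untargeted Volatilomics Analysis of Aging Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of untargeted GC-MS volatile metabolomics
    time courses, built around the workflow used to characterise aroma
    development during cigar aging. Provides internal-standard
    semi-quantification of peak areas, per-class ANOVA with Tukey compact
    letter displays, PCA for stage discovery, orthogonal partial least
    squares discriminant analysis (OPLS-DA) with VIP scores, cross-validated
    Q2 and permutation validation, differential-volatile screening by
    combined VIP, fold-change and p-value criteria, K-means clustering of
    unit-variance-scaled stage trends, hypergeometric metabolite set
    enrichment, and relative odor activity value (rOAV) profiling with a
    key-aroma-compound screen. A seeded synthetic data generator with known
    ground truth makes every stage testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
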