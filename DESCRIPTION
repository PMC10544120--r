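Package: drugTargetMR
Title: Drug-Target Mendelian Randomization and Colocalization from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cis-instrument selection for drug-target genes, two-sample
    Mendelian randomization (Wald ratio, fixed- and random-effects
    inverse-variance weighting, MR-Egger, generalized least squares for
    correlated instruments), heterogeneity and pleiotropy diagnostics,
    five-hypothesis approximate-Bayes-factor colocalization, and a
    synthetic two-sample GWAS generator with known ground truth for
    end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
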