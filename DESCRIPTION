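Package: TargetMR
Title: Drug-Target Mendelian Randomization with Colocalization and Mediation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization from two-sample
    GWAS summary statistics. Builds cis instruments around target genes
    (P-value cascade with greedy LD clumping), harmonizes exposure and
    outcome associations, and estimates causal effects with a suite of
    two-sample estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, weighted mode, MR-LASSO) plus Cochran's Q and Steiger
    directionality diagnostics. Includes single-causal-variant Bayesian
    colocalization via approximate Bayes factors with conditional H4,
    two-step MR mediation by the product-of-coefficients method,
    Hardy-Weinberg carrier-prevalence estimation for receptor-activating
    alleles, a seeded synthetic GWAS generator for end-to-end validation,
    and a study orchestrator producing tidy replicable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
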