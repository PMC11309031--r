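Package: mrmediate
Title: Two-Sample Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: reading and validating summary tables, allele
    harmonization with palindromic-SNP handling, instrument selection by
    p-value threshold, greedy LD clumping and F-statistic filtering, a
    five-estimator causal suite (multiplicative random-effects IVW, MR-Egger,
    weighted median, simple and weighted mode), sensitivity analyses
    (Cochran's and Rucker's Q, Egger intercept, MR-PRESSO global/outlier/
    distortion tests), Benjamini-Hochberg FDR adjustment, and two-step MR
    mediation with parametric-bootstrap intervals for the indirect effect and
    proportion mediated. Includes a synthetic GWAS summary-statistics
    generator with configurable causal, pleiotropic and mediation structure,
    and a config-driven pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
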