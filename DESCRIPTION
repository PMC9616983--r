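Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bidirectional two-sample Mendelian randomization on
    GWAS summary statistics: reading and validating summary-statistic and
    linkage-disequilibrium tables, instrument selection with p-value
    thresholding, cross-trait exclusion and greedy LD pruning, allele
    harmonization with palindromic-SNP handling, causal estimation by Wald
    ratio, inverse-variance weighting, MR-Egger regression, the weighted
    median estimator and an MR-PRESSO style outlier procedure, heterogeneity
    and influence diagnostics, analytic power calculation for continuous
    outcomes, grouped Benjamini-Hochberg false-discovery-rate adjustment,
    and a synthetic GWAS-pair generator with known causal effect for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
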