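Package: metagwaspower
Title: Power and Polygenic Score Accuracy of Multi-Study GWAS Meta-Analysis
    under Cross-Study Genetic Heterogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Closed-form statistical power and expected discovery counts for a
    fixed-effects meta-analysis of genome-wide association studies (GWAS)
    whose causal-SNP effects are imperfectly correlated across studies, and
    the theoretical out-of-sample R-squared of a polygenic score built from
    the meta-analysis effect estimates. Study designs are described by
    per-study sample sizes, per-study SNP heritabilities, a cross-study
    genetic-correlation (CGR) structure, and an independent-SNP genetic
    architecture. Includes attenuation reporting against the perfect-CGR
    benchmark, a design-grid evaluator for contour-style summaries, a
    reproduction catalog of published reference designs, and a seeded
    genotype-level simulator of the multi-study random-effects model that
    validates the closed forms empirically, including under violations of
    the equal-R-squared and shared-causal-loci assumptions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
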