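Package: protqtl
Title: Permutation-Based Protein-QTL and Variant-Group Analysis for Targeted
    Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical machinery for small case/control cohorts with a
    quantitative protein phenotype and targeted-panel genotypes: Monte-Carlo
    permutation tests with binomial confidence intervals on the permuted
    p-value, Box-Cox phenotype normalization, Spearman correlation screens
    with Bonferroni experiment-wise flags, exact Hardy-Weinberg equilibrium
    quality control, additive logistic case/control and linear protein-QTL
    association scans adjusted for age and sex with permutation verification
    of top hits, Gibbs-sampling haplotype phasing with variant-group
    assignment, Cochran-Armitage trend tests, and unweighted variant-burden
    genetic risk scores. Includes a synthetic cohort generator with
    haplotype-block genotypes, planted genetic effects and copula-correlated
    functional readouts, so every stage is testable end to end without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    vcfR
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
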