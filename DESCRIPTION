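Package: ascnassoc
Title: Association Testing for SNPs in Common Copy Number Variant Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Case-control association testing for SNPs located within common
    copy number variants (CNVs), using allele-specific copy number (ASCN)
    states such as A, AB, ABB or AAAB in place of the usual bi-allelic
    genotypes. Provides the analytic state-frequency and multiplicative
    relative-risk model for control and case populations, a case-control
    cohort simulator with bi-allelic genotype degradation and CNV
    calling-error injection, five logistic-regression likelihood-ratio test
    strategies (copy-number trend, bi-allelic and multi-allelic allele
    trends, the two degree-of-freedom Joint sum/difference model with
    unbiased odds-ratio recovery, and a general codominant model), a power
    and type-I-error simulation engine over scenario grids, and a real-data
    path from PennCNV calls plus B-allele frequencies to per-SNP association
    results with Hardy-Weinberg and missingness QC and multiple-testing
    correction via Bonferroni and the effective number of independent tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
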