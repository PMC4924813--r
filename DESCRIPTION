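Package: neuroqtl
Title: Imaging Genetics Association, Brain eQTL Regression, and
    Allele-Specific Transcription Factor Binding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline linking common variants at a copy-number
    variant locus to regional brain structure and gene regulation.
    Implements covariate-adjusted SNP-by-ROI linear regression with an
    aggregate sum-of-chi-square permutation test (per-SNP and max-T
    family-wise modes), genotype quality control (minor allele frequency,
    exact Hardy-Weinberg testing, EM-based pairwise linkage-disequilibrium
    r-squared, greedy tag-SNP selection), eQTL regression on brain
    expression averaged within individuals, transcription-factor/target
    correlation screening with a lack-of-fit F-test, and allele-specific
    position-weight-matrix scanning with fold-affinity and
    logical-consistency prioritization of candidate transcription factors.
    A synthetic-data generator produces genotype, covariate, phenotype,
    expression, motif, and flank-sequence fixtures with the statistical
    structure every downstream stage assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    emmeans,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
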