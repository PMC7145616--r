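Package: tseakit
Title: Tissue-Specific Enrichment Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for mapping human traits to candidate tissues from
    genome-wide association study (GWAS) summary statistics. Implements
    study- and variant-level quality control with the genomic inflation
    factor, linkage-disequilibrium-aware gene-based association P-values
    (sum of chi-squares with a weighted-chi-square null), tissue
    specificity scoring of expression panels (t- and z-scores),
    construction of thresholded trait-associated gene sets, one-sided
    chi-square tissue enrichment tests, permutation-based gene set
    enrichment validation with normalized enrichment scores, duplicate
    study detection, cross-study comparison, and a seeded synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
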