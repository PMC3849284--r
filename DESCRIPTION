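Package: snpkin
Title: Genomic Inbreeding and Kinship Estimation from Optimized SNP Panels
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimation of genomic inbreeding and pairwise kinship from
    biallelic SNP genotypes using the allele-frequency-weighted
    identity-by-state relationship matrix, together with the supporting
    pipeline used in livestock panel-design studies: PLINK text PED/MAP
    input and output, marker and sample quality control (Mendelian-error,
    per-line minor-allele-frequency, call-rate, sex-chromosome and
    missingness filters), windowed r-squared linkage-disequilibrium
    pruning, pedigree-based inbreeding and additive relationships
    (Meuwissen-Luo recursion and the tabular method),
    opposing-homozygote paternity verification, and chromosome-weighted
    bootstrap evaluation of reduced SNP panels. A gene-dropping
    simulator with tracked identity-by-descent provides pedigreed
    datasets with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
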