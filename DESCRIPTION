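Package: dlahap
Title: Three-Locus DLA Haplotype Phasing, Diversity and Donor-Coverage Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dog leukocyte antigen (DLA) three-locus
    haplotypes (DLA-88, DLA-12/88L, DLA-DRB1). Parses and validates MHC-style
    allele nomenclature, reconstructs haplotypes from unphased breed-stratified
    genotype tables by tiered homozygote-anchored phasing with an
    expectation-maximisation cross-check, computes per-breed haplotype
    frequency tables and diversity statistics (observed and expected
    heterozygosity, inbreeding coefficient, rarefied haplotype richness,
    Monte-Carlo Hardy-Weinberg tests), models homozygous-donor
    haplotype-matched transplantation coverage, and summarises breed structure
    by principal component analysis of haplotype frequencies. Includes a
    seeded synthetic cohort generator emulating breed-stratified DLA survey
    data so every stage is testable without per-dog source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
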