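Package: eduroh
Title: Educational Assortment, Migration, and Genomic Homozygosity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to study how educational attainment shapes genomic
    homozygosity through migration and assortative mating. Provides a
    two-generation synthetic-cohort simulator (ordinal educational
    attainment with spousal assortment, education-dependent migration
    distances, spatial allele-frequency clines, and parental kinship
    decaying with birthplace distance), a runs-of-homozygosity caller with
    variance-inflation-factor LD pruning and the F_roh autozygosity
    statistic, great-circle birthplace distances, contingency and rank
    statistics for educational assortment, permutation-based R-squared
    change tests, Sobel mediation tests, ancestry principal components
    from standardized genotypes, and a moderated-correlation model for
    the decay of the ancestry-geography correlation with parental
    education. Includes PLINK text and binary genotype input/output and
    an end-to-end pipeline reproducing the study's table shapes on
    simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite
Config/testthat/edition: 3
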