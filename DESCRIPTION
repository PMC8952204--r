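Package: exomestrat
Title: Extreme-Phenotype Exome Stratification by Pairwise Allelic Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for exome-scale stratification of phenotypically
    extreme groups of healthy individuals. Performs per-comparison call-rate
    filtering, pairwise allelic Fisher exact scans between constitution groups,
    label-shuffling permutation filtering with empirical p-values, allele-frequency
    profile assignment, three-level cross-cohort replication, contrasts against a
    background control population, GWAS-catalog risk-allele stratification with a
    resampling enrichment null, and simulation-based power analysis of the
    two-group allelic Fisher test. Includes a Hardy-Weinberg genotype simulator
    with planted between-group frequency differences and a synthetic risk-allele
    catalog so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
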