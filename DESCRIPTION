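Package: snppanel
Title: Diagnostic SNP Panel Design and SNP-Based Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing small species-diagnostic SNP panels from
    genome-wide biallelic genotypes and for assigning individuals to species
    with the resulting panels. Covers the full workflow for a multi-species
    plant complex: simulation of structured populations under the
    Balding-Nichols model, VCF and genotype-table input, hard-filter cascades
    (depth, genotype quality, allele balance, minor allele count,
    missingness), per-locus diversity statistics (observed heterozygosity,
    unbiased gene diversity, polymorphic information content) and
    Weir-Cockerham F_ST with bootstrap confidence intervals, F_ST-window
    panel selection scored by principal component analysis and cluster
    silhouette, consensus genotyping from replicated assay runs with Match
    Score error estimation, and species assignment via Bowcock allele-sharing
    distance, UPGMA dendrograms, principal coordinates analysis, an
    ADMIXTURE-style EM with cross-validated selection of the number of
    clusters, multilocus genotype matching and frequency-based assignment
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
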