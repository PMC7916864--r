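Package: popgenld
Title: Population Structure, Inbreeding and Linkage-Disequilibrium Analyses
    for Livestock Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic characterisation of farmed-animal
    populations from whole-genome SNP genotypes. Reads multi-sample VCFs into
    a dosage matrix, applies standard site filters (minor allele frequency,
    missing rate, site quality), and computes per-group diversity summaries,
    excess-homozygosity and pedigree inbreeding coefficients, runs of
    homozygosity and F_ROH, Nei's standard genetic distance, Weir-Cockerham
    Fst, hierarchical AMOVA with permutation tests, composite (Burrows)
    linkage-disequilibrium r2 with distance-binned decay curves, and
    LD-based effective-population-size trajectories via Sved's expectation.
    Includes simulators (Balding-Nichols structured populations, forward
    Wright-Fisher with recombination, planted autozygous tracts, designed
    pedigrees) that provide ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
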