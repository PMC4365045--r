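Package: mitophylogeo
Title: Mitochondrial Phylogeography: Haplogroup Classification, Clade
    Dating and Spatial Analysis of Mitogenome Variation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for phylogeographic analysis of human mitochondrial
    genomes: parsing and normalisation of mtDNA variants in the standard
    rCRS-relative nomenclature (including VCF conversion and hotspot
    exclusion masks), haplogroup classification against a PhyloTree-style
    haplogroup tree with discovery of new sub-haplogroups, founder-age
    estimation of clades by the rho statistic with the Saillard heuristic
    standard error and by maximum-likelihood clock dating, control-region
    diversity indices, pairwise PhiST distances with classical
    multidimensional scaling, ordinary kriging of haplogroup-frequency
    surfaces, and a seeded synthetic-mitogenome generator for
    simulation-based validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    vcfR
Suggests:
    Biostrings,
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
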