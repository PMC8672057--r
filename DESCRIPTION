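Package: mitoCensus
Title: Comparative Characterization of Annotated Fungal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated fungal mitochondrial
    genomes: redundancy filtering by greedy identity clustering, feature
    classification into core genes, introns, homing endonuclease genes (HEGs),
    uORFs and plasmid-derived polymerase genes, circular-aware genic and
    intergenic length accounting by overlap removal, accessory-element overlap
    statistics, similarity-network construction using the identity of the
    longest continuous local alignment, correlation and rank-sum statistics,
    patristic distance matrices, and a synthetic annotated-mitogenome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
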