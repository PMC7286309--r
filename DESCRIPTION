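Package: ackpaint
Title: Genomic-Block Painting and Rearrangement Phylogenetics for Crucifer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects syntenic blocks between crucifer genomes by collinearity
    chaining in gene-rank space, separates orthologous from whole-genome
    duplication (At-alpha) derived blocks by their median synonymous
    substitution rate (Ks), projects the orthologous blocks onto the 22
    genomic blocks of the ancestral crucifer karyotype (ACK) to produce a
    painted karyotype with sub-block indices and inversion flags, and turns
    shared non-ancestral block adjacencies into binary characters scored on
    candidate backbone topologies by Fitch parsimony. Includes a synthetic
    genome-evolution simulator (whole-genome duplication, biased
    fractionation, inversions, translocations, fissions, fusions along a
    tree) that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
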