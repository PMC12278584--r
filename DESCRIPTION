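Package: gtdiscord
Title: Gene-Tree/Species-Tree Discordance Experiments with Mutation-Selection Codon Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying gene-tree/species-tree discordance in
    protein-coding phylogenomic data. Simulates multispecies-coalescent gene
    trees and codon alignments, refits candidate gene-tree topologies under
    nucleotide (GTR+G) and mutation-selection codon models (FMutSel0 and a
    SelAC-style stabilizing-selection model), tests whether models prefer
    topologies less discordant with a reference species tree, builds
    quartet-score coalescent species trees from alternative gene-tree sets,
    and flags anomaly-zone and otherwise difficult nodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
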