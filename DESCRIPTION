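Package: synmrl
Title: Species-Tree Inference from Whole-Genome Microsynteny Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers species trees from whole-genome microsynteny: pairwise
    collinear block detection from gene order and homology hits, assembly of
    an undirected synteny network, clustering into synteny clusters, matrix
    representation of cluster phylogenomic profiles as binary characters, and
    maximum-likelihood tree inference under a two-state Markov (Mk) model
    with free state frequencies and FreeRate among-character rate
    heterogeneity. Includes a stochastic birth-death-rearrangement simulator
    of gene-family syntenic networks along a dated species tree for
    validating the approach, supertree split encoding of well-supported
    bipartitions, conserved single-copy synteny cluster (CSSC) marker
    selection, and Robinson-Foulds topology distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
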