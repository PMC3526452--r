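Package: linchrom
Title: Linearization of Ancestral Multichromosomal Genomes from Weighted Adjacencies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts, from a weighted set of candidate ancestral gene
    adjacencies with per-gene copy-number bounds, a maximum-weight subset
    that can be realized as a multichromosomal genome whose chromosomes may
    be linear or circular. The optimum is computed exactly in polynomial
    time by reducing the degree-constrained subgraph problem (2m-matching)
    to maximum-weight matching via a Tutte-style gadget, then decomposing
    the selected adjacency graph into chromosomes by Eulerian trails.
    Includes exhaustive brute-force oracles (including 2,3-uniform
    hypergraph covering and row-removal solvers at toy scale), a
    planted-genome synthetic instance generator, TSV input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
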