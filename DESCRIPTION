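Package: dcjindel
Title: Capping-Free DCJ-Indel Distances for Natural Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome rearrangement distances under the double-cut-and-join
    (DCJ) model with insertions and deletions, computed without capping of
    linear chromosome ends. Provides a closed-form restricted DCJ-indel
    distance for genome pairs under a resolved homology, built on a
    component decomposition of the multi-relational diagram; an integer
    linear program that minimizes the distance over maximal (or exemplar /
    intermediate) gene-family matchings for natural genomes with ambiguous
    families; a rate-driven genome-pair evolution simulator with Zipf
    indel and duplication lengths; brute-force oracles (breadth-first
    search over rearrangement scenarios, exhaustive matching enumeration)
    for verification; and a UniMoG text format reader and writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
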