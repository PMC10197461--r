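Package: minidex
Title: Minimizer-Digest Run-Length BWT Indexing and Read Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compressed pangenome indexing and streaming read classification.
    Reference collections are reduced by minimizer digestion (optionally
    re-encoded over a minimizer alphabet in which every possible k-mer is one
    symbol) and indexed with a run-length encoded Burrows-Wheeler transform,
    a thresholds structure for jump-directed backward search, and a sampled
    document array holding a class label at every run boundary. Queries
    stream pseudomatching lengths (and, with suffix-array samples retained,
    exact matching statistics) right-to-left with pause/resume support.
    Classification layers cover binary presence calls from a null
    pseudomatching-length threshold with windowed majority voting,
    multi-class calls by aggregating document-array labels, contamination
    scanning of assembly contigs, and adaptive-sampling style batch
    decisions. Seeded synthetic pangenome and read simulators make the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
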