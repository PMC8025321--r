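Package: simplitigr
Title: Simplitig and Unitig Representations of de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes maximal simplitigs from k-mer sets by greedy
    vertex-disjoint path cover of the node-centric de Bruijn graph, and
    maximal unitigs by compaction along non-branching nodes, in both the
    uni-directed and the bi-directed (canonical k-mer) strand models.
    Provides exactly-once verification of k-mer content, NS/CL accounting
    with bound and identity checks, bits-per-k-mer storage metrics with xz
    compression, synthetic genome and pan-genome simulators, a brute-force
    minimum path cover oracle for small graphs, desk-scale scaling and
    storage experiments, and a ProphAsm-style command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
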