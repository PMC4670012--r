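Package: slimscout
Title: Discovery and Enrichment Statistics for Short Linear Motifs in
    Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of over-represented short linear motifs
    (SLiMs) in sets of protein sequences, query-restricted discovery, and
    occurrence/enrichment statistics for known motifs given as SLiM
    regular expressions. Statistics are homology-aware: proteins are
    clustered into Unrelated Protein Clusters (UPCs) from pairwise local
    alignment E-values, and motif support is counted per cluster so that
    shared ancestry is not mistaken for convergent evolution. Supports
    disorder-score, sequence-feature and relative-local-conservation
    masking, synthetic dataset generation for benchmarking, and
    protein-protein interaction network annotation with motif occurrence
    styling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
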