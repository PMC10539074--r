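Package: tadcons
Title: Conserved and Species-Specific TAD Boundary Detection Across Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects conserved and species-specific topologically associating
    domain (TAD) boundaries across multiple genomes. TAD intervals are reduced
    to merged boundary regions; cross-species conservation evidence is
    collected through two channels, collinear (syntenic) gene anchors and
    direct boundary-sequence alignment with MinHash-distance-adapted
    stringency presets; evidence-weighted boundary pairs are assembled into a
    multi-species boundary graph, clustered with a Markov Cluster (MCL)
    implementation, and summarised as phylogenomic presence profiles. A
    seeded synthetic-clade generator produces genomes, annotations and TAD
    calls with ground-truth conservation labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    grDevices,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap,
    optparse
Config/testthat/edition: 3
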