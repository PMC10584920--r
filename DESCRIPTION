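Package: py1h
Title: Quantification and Event Calling for Paired Yeast One-Hybrid Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis stack for paired yeast one-hybrid (pY1H) screens that
    probe cooperative and antagonistic DNA binding between transcription
    factor pairs. Quantifies 1536-colony agar plate images (cropping, grid
    detection, colony segmentation, area and intensity measurement), computes
    reporter signal scores and cooperativity/antagonism indices against
    empty-empty controls, applies quality-control and event-calling rules
    under the 1-AD and 2-AD assay designs, scans promoters with position
    weight matrices using exact dynamic-programming p-values and merges hits
    into core motifs, performs degree-preserving bipartite network
    randomization against ChIP or motif evidence, scores tissue/cell-type
    expression specificity and co-expression from cluster-level expression
    matrices, expands candidate TF pairs by sequence homology, and confirms
    strain identity from barcoded-well amplicon alignments. Includes seeded
    synthetic-data generators for every input so the full pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    methods,
    Biostrings,
    EBImage,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
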