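Package: hgtsieve
Title: Detection and Quantification of Horizontal Gene Transfer in
    Anaerobic Gut Fungal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and quantifying horizontal
    gene transfer (HGT) in transcriptome-predicted proteomes of anaerobic gut
    fungi (Neocallimastigomycota). Predicted peptides are searched against
    taxonomy-partitioned reference protein databases with an internal
    Smith-Waterman engine reporting Karlin-Altschul bit scores and E-values;
    candidates are called with the h_U HGT index (best non-fungal minus best
    fungal bit score), clustered at 95% identity, and confirmed by
    neighbor-joining phylogenies with bootstrap-supported clade-nesting tests
    that also assign the donor lineage. Confirmed transfers are filtered by
    per-genus replication, consolidated into distinct events, compared with a
    reference event catalog, and summarized. The package also provides a
    planted-transfer simulator with a truth table for end-to-end benchmarking,
    the rule-based two-tier genus classifier for LSU amplicon reads, and
    rule-based cellulosome candidate calling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
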