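Package: pemseq
Title: Quantification of CRISPR Editing Outcomes and Off-Target Hotspots
    from PEM-seq Libraries
Version: 0.1.0
Authors@R:
    person("PEM-seq", "Maintainers", email = "maintainers@pemseq.dev",
           role = c("aut", "cre"))
Description: Analysis of primer-extension-mediated sequencing (PEM-seq)
    libraries for genome editing assessment. Cleans and demultiplexes
    paired reads, extracts the 14-bp random molecular barcode (RMB) from
    the bridge adapter, calls bait-to-prey junctions from split
    alignments, classifies every sequenced molecule as germline, indel
    (small indels, large deletions, inversions) or genome-wide
    translocation, collapses PCR duplicates by barcode clustering at edit
    distance 2, and computes editing efficiency against an uncut control
    with transfection-efficiency correction. Off-target hotspots are
    identified genome-wide by local-Poisson peak enrichment of
    translocation junctions, cryptic target-site matching with PAM rules,
    and replicate recurrence, and scored per 100,000 editing events.
    Closed-form gel-based indel estimators (RFLP, T7EI, single-cell RFLP)
    and a ground-truthed synthetic library simulator are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    Rsamtools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
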