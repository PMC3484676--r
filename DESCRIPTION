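Package: regulonscan
Title: Replicate Peak Reconciliation, Calibrated Motif Scanning, and
    Regulon Conservation for ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of genome-wide transcription-cofactor
    binding from ChIP-seq peak calls: reconciliation of two biological
    replicates into concordant (Class A) and replicate-specific (Class
    B/C) peaks by summit distance, promoter-proximal annotation of peaks
    to transcription start sites, position weight matrix scanning with
    exact score-distribution p-values, scramble-calibrated motif presence
    calls, motif constellation and per-category enrichment profiling, and
    cross-species regulon overlap through ortholog families. Includes a
    synthetic-data generator that emits genomes, annotations, replicate
    peak lists and motif-planted promoters with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    igraph,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
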