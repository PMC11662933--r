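Package: snordnet
Title: Consensus Dysregulated Genes and Predicted SNORD116 Targeting in
    Isogenic Prader-Willi Syndrome Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Downstream analysis pipeline for isogenic Prader-Willi
    syndrome (PWS) deletion models: low-count and significance filtering
    of differential-expression tables, three-design per-deletion
    consensus and cross-model shared-gene determination, a directional
    overlap permutation test, merging of per-window C/D box snoRNA
    target predictions into binding events by a consecutive-window rule,
    covariate-matched control-list resampling enrichment, snoRNA
    box-relative positional profiles, genomic feature coverage and
    metagene density on target genes, and hypergeometric
    over-representation with fold enrichment. Includes a synthetic-data
    generator producing count matrices, differential-expression tables,
    annotation, sequence, and window-score tables with planted effects
    so the whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    fgsea,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
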