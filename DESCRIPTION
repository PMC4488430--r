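Package: spetseq
Title: Single Primer Enrichment Targeted RNA-Seq: Panel Design, Assay
    Simulation and Gene Fusion Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single primer enrichment technology (SPET) targeted
    RNA sequencing of gene fusions. Designs exon-boundary and tiled capture
    probes on both strands of the double-stranded cDNA from a GTF/FASTA gene
    annotation, simulates the molecular steps of the assay (cDNA
    fragmentation, adapter ligation, probe hybridization and polymerase
    extension, paired-end sequencing) with full ground-truth provenance,
    and calls fusion junctions from split reads anchored by a single
    targeted partner, together with on-target enrichment metrics. Because a
    probe only needs to hybridize to one gene of a fused pair, fusions are
    detectable even when the partner gene is absent from the panel; the
    simulator and caller make that property testable end to end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    stringi,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
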