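Package: rrscan
Title: Identification of Reprogramming-Resistant Genes and Regions in
    Nuclear-Transfer Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window differential expression and fold-change
    classification of embryonic genome activation (EGA) failure in somatic
    cell nuclear transfer (SCNT) embryos. Provides window construction over
    a genome layout, RPM/FPKM/VST normalisation of count matrices, a
    replicate-aware negative-binomial gene test and pooled Fisher window
    test with Benjamini-Hochberg correction, the EGA-ON/OFF and PFF-ON/OFF
    threshold taxonomy for genes, merged genomic regions and repeat
    elements, treatment-restoration scoring, input-normalised histone-mark
    meta-profiles over classified features, CpG methylation aggregation
    from bisulfite calls, and a seeded synthetic-data generator that plants
    ground-truth resistant features so every stage of the analysis is
    verifiable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
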