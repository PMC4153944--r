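Package: perimeth
Title: RRBS Methylome Profiling and Sliding-Window DMR Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for pooled two-group reduced-representation
    bisulfite sequencing (RRBS) studies of the perinatal intestine. Provides
    in silico MspI digestion and fragment size selection with CpG-recovery
    accounting, CpG-island detection, global and regional methylome
    summaries (context breakdown, methylation quintiles, metagene profiles,
    chromosome-feature correlations), a sliding-window differentially
    methylated region (DMR) caller based on per-site and aggregate Fisher
    exact tests with Benjamini-Hochberg false-discovery-rate control,
    DMR annotation and cross-matching, amplicon bisulfite validation
    statistics (HiSeq-BSP versus Sanger clone concordance, per-CpG
    coefficients of variation, amplicon re-calling) and delta-delta-Ct
    qPCR analysis. A synthetic-data generator produces genomes, methylomes
    and beta-binomial count tables with planted DMRs so every stage can be
    exercised and benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    IRanges,
    fgsea,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
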