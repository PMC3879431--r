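Package: stressmem
Title: Classification of Dehydration-Stress Transcriptional Memory Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for classifying transcriptional stress
    memory from repeated-dehydration RNA-Seq experiments in Arabidopsis
    thaliana. Genes are gated per contrast (first stress versus watered,
    third stress versus first stress) by a three-criterion significance
    rule (FDR q-value, log2 fold-change magnitude, and an expression floor
    at the 25th percentile of pooled FPKM), then combined into a nine-class
    memory / non-memory / late-response typology. Downstream stages
    cross-tabulate classes against functional-category annotations,
    compute Venn memberships, and cluster binary transcription-factor
    annotation matrices bidirectionally with UPGMA average linkage on
    Euclidean distances. A synthetic-data generator plants recoverable
    class structure so the entire pipeline is testable without raw
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
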