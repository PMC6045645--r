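Package: betameth
Title: Beta-Binomial Differential DNA Methylation Analysis for RRBS Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential DNA methylation analysis chain for reduced
    representation bisulfite sequencing (RRBS) count data: strand merging of
    CpG cytosine counts, per-CpG beta-binomial likelihood-ratio tests with
    windowed Stouffer p-value combination and Benjamini-Hochberg FDR control,
    aggregation of significant CpGs into directional differentially methylated
    regions (DMRs), TSS association and enrichment of hyper-/hypomethylated
    CpGs within epigenomic interval sets, position-weight-matrix scanning,
    group comparison of array-style beta-value matrices, and a simplified
    negative-binomial differential-expression stage integrated with promoter
    methylation changes. Includes a synthetic-data generator producing every
    pipeline input with a known-truth record for calibration and recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
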