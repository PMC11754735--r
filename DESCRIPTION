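Package: termwin
Title: Definition and Characterization of RNA Polymerase II Transcription
    Termination Windows from Nascent-Transcription Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls RNA polymerase II transcription-termination windows
    genome-wide from strand-specific, single-nucleotide nascent-transcription
    coverage (mNET-seq-style tracks of CTD-T4ph signal). Provides gene
    preselection from GTF annotation (non-overlapping genes with isolated
    3' ends), replicate averaging, 150-bp signal extension, a two-tier
    broad-enrichment caller, cross-study consensus and merging, three-way
    window classification (gene-end, premature, other), and the accompanying
    characterization metrics: scale-regions metagene matrices with unit-max
    scaling, per-gene log2 PAS/TSS signal ratios, and activity-quintile
    stratified profiles. A calibrated Poisson coverage simulator with planted
    termination structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
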