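Package: mirarms
Title: Small RNA Profiling with Stem-Loop Arm Splitting and Repeat RNA Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-usable pipeline for small RNA sequencing profiling
    in Drosophila neurodegeneration models: adapter trimming and length
    filtering of raw reads, 0/1-mismatch matching against reference sequence
    sets on both strands, hierarchical mutually exclusive annotation across
    six reference categories, assignment of stem-loop reads to 5p and 3p
    mature miRNA arms by an optimal split-position search, negative binomial
    exact-test differential expression with median-of-ratios normalization
    and dispersion estimation augmented by an independent reference control
    set, head versus whole-body enrichment classification, and edit-tolerant
    detection of small CAG-repeat RNAs (sCAG) in polyglutamine transgene
    models. A seeded synthetic data generator produces reference bundles,
    count matrices and FASTQ read sets carrying the statistical structure
    the downstream analysis assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
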