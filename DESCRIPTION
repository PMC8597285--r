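Package: corefitness
Title: Core-Fitness and Common-Essential Gene Identification from Pooled
    CRISPR-Cas9 Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint analysis of gene dependency matrices from multiple pooled
    CRISPR-Cas9 knock-out screens to identify genes that are essential across
    tissues and genomic contexts. Implements the two-step Adaptive Daisy Model
    (ADaM) for supervised identification of core-fitness genes, four variants
    of the unsupervised Fitness Percentile (FiPer) method with a kernel-density
    classifier for common-essential genes, a baseline daisy-model benchmarking
    framework (matched-TPR false-positive-rate ratios, dependent-cell-line and
    fitness-effect summaries, recall and Jaccard comparisons), and a synthetic
    screen generator with planted core, context-specific and never-essential
    genes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
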