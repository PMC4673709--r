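Package: wormcnv
Title: Copy-Number Variant Detection and Population Dynamics in
    Experimental Caenorhabditis elegans Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting gene copy-number variants (CNVs) in pooled
    Caenorhabditis elegans populations and tracking their population
    frequencies over generations of experimental evolution. Implements
    bottom-up t-test segmentation of array-CGH log2-ratio profiles with
    quantile normalization and amplified/deleted classification, copy-number
    estimation from qPCR cycle thresholds via the efficiency-corrected
    delta-delta-Ct method with percentile bootstrap confidence intervals,
    Hardy-Weinberg frequency estimation from single-worm PCR presence/absence
    counts, convergent-CNV detection by genomic interval intersection,
    unequal crossing-over breakpoint localization between flanking repeats,
    and drift-versus-selection population-genetic calculations (full-sib
    inbreeding recursion, neutral fixation theory, mutation-pressure
    trajectories, Wright-Fisher simulation). A synthetic-data module
    generates every input with known ground truth, and published CNV
    catalogs are shipped as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
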