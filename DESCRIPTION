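Package: ctcfconst
Title: Constitutive CTCF/Cohesin Binding-Site Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies and characterizes constitutive CTCF/cohesin binding
    sites from ChIP-seq peak sets across many cell lines. Provides position
    weight matrix scanning with exact score-distribution p-values, occurrence
    aggregation and the >90 percent constitutive-site rule, site classification
    against cohesin (Rad21/Smc3) peaks, genomic-context annotation (TSS
    distance, CpG-island density, co-factor overlap), positional k-mer
    discovery of full-spectrum flanking motifs, cross-species conservation
    scoring from multiple-alignment blocks, ChIA-PET interaction enrichment
    with fractional pair-type counting, and topological-domain boundary
    distance analysis, together with a synthetic-data generator that emulates
    the statistical structure of each input so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    IRanges,
    GenomicRanges,
    Biostrings,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
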