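Package: chaconnectome
Title: CAGE-Defined Highly Active Enhancers, Their Chromatin Connectome,
    and Variant-to-Gene Causal Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls CAGE-tag highly active (CHA) enhancers from H3K27ac peaks
    and CAGE tag matrices, builds the enhancer-promoter connectome from
    HiChIP loop tables, identifies hub regulatory units, quantifies
    RNA-polymerase pausing from run-on sequencing coverage, tests variant
    enrichment in regulatory elements (extreme-tail Fisher, hypergeometric,
    binomial projection and relative-distance Kolmogorov-Smirnov tests),
    and screens variant-mapped genes with inverse-variance-weighted
    Mendelian randomization.  A synthetic-data module generates every input
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
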