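Package: radopt
Title: Optimized RAD-Seq Experimental Design and Pooled-Library Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and evaluate reduced-representation (RAD-seq/ddRAD)
    sequencing experiments for plant genomes. Performs in-silico restriction
    digestion with degenerate (IUPAC) recognition sites, ranks first-round
    enzyme combinations by genomic fragment recovery within a size window,
    and searches second-round enzyme sets that cut every chloroplast- and
    rRNA-derived fragment while sparing genomic ones. Models the dilution of
    sequencing reads by high-copy organellar DNA, plans per-sample coverage,
    demultiplexes inline-barcoded paired-end pools, summarises read balance,
    fragment-length recovery and depth consistency, and applies population
    filtering and chi-square segregation tests to variant calls, including
    autotetraploid expectations with double reduction. A simulator generates
    genomes with planted restriction fragments, barcoded read pools and
    segregating-population genotypes for fully specified end-to-end tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
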