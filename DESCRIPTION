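Package: meiohic
Title: Meiotic Hi-C Contact Map Analysis for Bouquet Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds, filters and balances restriction-fragment Hi-C contact
    matrices for small fungal genomes and quantifies meiotic chromosome
    architecture: the telomere-bouquet "alignment index" measured on
    anti-diagonal contacts, contact-probability P(s) decay curves with
    Loess-smoothed derivatives and second-derivative shoulder detection,
    percent-rank and subtraction heatmap transforms, and punctate chromatin
    loop calling with a donut-filter local-expected test on Knight-Ruiz
    balanced matrices. Includes a synthetic contact-map generator that
    plants bouquet arm alignment, Rabl centromere clustering and cohesin
    loop grids with a full ground-truth record, so every analysis stage can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
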