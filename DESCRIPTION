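Package: mirshift
Title: miRNA Abundance Shifts Between Tumour and Serum Compartments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled small-RNA sequencing studies of
    microRNA redistribution between tumour tissue and blood serum under a
    therapeutic intervention. Quantifies miRNA libraries as RPKM, summarises
    read-class composition, calls treated-versus-control abundance shifts per
    compartment with a two-library conditional exact test and
    Benjamini-Hochberg correction, partitions affected miRNAs into
    common/tumour-specific/serum-specific sets, ranks qPCR validation
    candidates with the total-score over total-fold (TS/TF) statistic,
    reproduces Z-score/UPGMA heat-map clustering, and analyses stem-loop
    RT-qPCR validation data (dilution-series efficiency, geNorm reference-gene
    stability, efficiency-corrected relative expression, group tests). A
    seeded synthetic-data generator emulating the study design makes every
    stage testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
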