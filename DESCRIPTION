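Package: poolmapr
Title: Bulk-Segregant Mapping-by-Sequencing for Pooled F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for mapping-by-sequencing of a recessive
    causal mutation from pooled bulk-segregant data. Simulates an
    interspecific F2 cross with recombination (Haldane map) and pooled
    short-read allele counts, computes per-pool allele-frequency ratios and
    sliding-window per-chromosome profiles, detects candidate regions,
    applies zygosity and novelty candidate filters, predicts protein-level
    variant effects on coding sequences, designs and evaluates CAPS/dCAPS
    restriction genotyping assays, runs Mendelian segregation chi-square
    tests, and provides expression quality-control utilities (TPM
    normalization, replicate-consistency biclustering, stage-wise DE-list
    intersection, delta-delta-Ct relative expression).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
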