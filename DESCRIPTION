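Package: ribotag
Title: Cell-Type Translatome Enrichment Analysis for Paired Ribotag RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for Ribotag/TRAP translatome profiling with
    paired immunoprecipitated (IP) and total-RNA libraries. Provides relative
    log expression normalization, gene-wise negative-binomial generalized
    linear models with fraction-by-condition interaction contrasts (Wald and
    likelihood ratio tests), a contamination-aware two-arm filtration of
    injury-regulated cell-type transcripts, marker-overlap statistics
    (representation factor and hypergeometric tail), resampling z-scores for
    regulon gene-set overlap, gene-set regulation summaries, delta-delta-Ct
    qPCR quantification, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
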