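Package: painlang
Title: Quantitative Semantic Analysis of Chronic Pain Narratives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts open-ended patient interview transcripts into
    quantitative measures of the chronic pain experience. Patient speech is
    segmented into sentences, embedded in a semantic vector space, and
    compared by cosine similarity against anchor/antithesis sentence pairs
    derived from validated pain questionnaires. Each interview-by-probe
    similarity distribution is reduced to its 95th-percentile robust
    maximum, and the cohort-level score table is analysed with exact
    two-sample Kolmogorov-Smirnov tests, Benjamini-Hochberg false discovery
    rate correction, and Spearman correlations against numerical rating
    scale (NRS) and visual analog scale (VAS) pain intensity, including a
    high/low-pain group comparison. A seeded synthetic-cohort generator
    with a latent pain-severity variable makes every pipeline stage
    testable without access to confidential interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
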