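Package: emonet
Title: Emotional Co-Occurrence Networks and Affective Complexity of Short Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds valence- and emotion-annotated word co-occurrence networks
    from corpora of short texts, profiles the eight basic emotions against
    resampled baselines, and quantifies the emotional entropy of valence
    transition sequences together with a triad-based measure of emotional
    complexity (the affective analog of structural balance). Observed
    statistics are tested against Shuffled and Uniform label-randomization
    null models with z-scores. Includes a seeded synthetic-data generator
    producing pseudo-word lexicons, note-like corpora and emotional-recall
    word lists with tunable valence mixtures and transition structure, so the
    whole pipeline can be exercised without access to sensitive corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
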