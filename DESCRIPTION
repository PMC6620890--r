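Package: tuitvig
Title: Behavioral and Linguistic Analysis of Spanish-Language Tweet Corpora for Depression Infoveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for screening Twitter corpora for signs of
    depression in Spanish-language messages. Implements corpus reading and
    filtering from JSON-lines, keyword and profile-based user screening,
    Twitter-aware tokenization, dictionary-based part-of-speech and pronoun
    profiling, lexicon scoring of negations, six basic emotions and dual
    (binary and graded) sentiment polarity, timezone-adjusted diurnal and
    weekly activity profiles, and the statistical comparison layer
    (chi-square, Welch t from raw data or summary statistics, Mann-Whitney U,
    and split-plot repeated-measures ANOVA with Greenhouse-Geisser
    correction). A synthetic two-population corpus generator with known
    linguistic and behavioral structure makes every stage testable without
    redistributable Twitter data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
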