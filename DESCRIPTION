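Package: ambinorm
Title: Dominance and Zeugma-Based Similarity Norming of Ambiguous Words
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses for two offline norming paradigms for lexically
    ambiguous words: meaning/sense dominance scoring from rater-classified
    free associates (top-two sense proportions p1, p2 and the score
    (p1 - p2)/p1, with interrater reliability and response-consistency
    statistics), and zeugma-based 1-7 meaning-similarity ratings across a
    homonym/polyseme/unambiguous continuum (participant and item
    exclusions, item and condition statistics, leave-one-out
    inter-annotator agreement, Bonferroni-corrected pairwise tests). A
    companion pipeline compares the human norms with contextual-encoder
    metrics: per-layer cosine distance between target-word and anaphor
    span embeddings and masked-anaphor surprisal, evaluated through
    layer-wise correlations and nested linear mixed-model comparisons. A
    seeded synthetic-data generator and a deterministic toy encoder make
    the full pipeline reproducible without human data or pretrained
    weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
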