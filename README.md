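# ambinorm

Analyses for offline norming of lexically ambiguous words, and for
comparing the resulting human norms with metrics from a contextual
language encoder.

Most English words carry more than one meaning. Homonyms (*bank*,
*calf*) have unrelated meanings of separate origin; polysemes
(*chicken*, *cotton*) have related senses of shared origin, either
regular (productive metonymic relations such as container/contents) or
irregular (metaphorical, analogical relations); unambiguous words anchor
the single-meaning end of the continuum. Psycholinguistic experiments on
ambiguity resolution need two quantities normed ahead of time: how
**dominant** each meaning of a word is, and how **similar** a word's
meanings are to each other. `ambinorm` implements both norming analyses
and a computational companion, for researchers preparing ambiguous-word
stimuli or benchmarking language models against human sense-similarity
judgments.

## What it computes

**Dominance from classified free associates.** Participants type two
free associates to each word; two raters classify every response against
the word's 2–5 candidate senses. With `p1 ≥ p2` the proportions of
classified responses aligned with the top two senses, the dominance
score is

    D = (p1 − p2) / p1,   D ∈ [0, 1]

`D = 0` means perfectly balanced meanings, `D = 1` a completely dominant
one; `D ≤ 0.75` is the conventional cutoff for calling a word
meaning-balanced. The module also reports interrater coverage and
consistency and the tendency of a participant's first and second
responses to tap the same meaning.

**Similarity from zeugma ratings.** Each item is a single sentence that
forces both meanings of the target word onto one referent ("*Mildew
spray removed the MOLD and concrete was poured into one.*"); felt
infelicity scales with sense distance, so 1–7 similarity ratings of the
target and its anaphor order items along the ambiguity continuum. The
module applies the participant exclusions (a rater whose Homonym and
Unambiguous condition means differ by ≤ 0.5 was not discriminating),
item exclusions, item statistics (M, SD, SEM = SD/√n), condition
statistics with pairwise Welch t tests under Bonferroni correction, and
leave-one-out inter-annotator agreement (per-rater Spearman ρ against
the mean of the remaining raters).

**Encoder metrics.** For each zeugma sentence, the per-layer cosine
distance `1 − cos(target, anaphor)` between span embeddings (subword
pieces averaged) and the masked-anaphor surprisal `s = −log p`. Items
with multiword anaphors ("a lot") are excluded. Layer-wise Pearson
correlations relate cosine distance to human item means, and nested
linear mixed models (random intercept for the anaphoric expression, ML
estimation, likelihood-ratio tests, Bonferroni over the two metrics) ask
whether the metrics track condition and explain human similarity beyond
it. A deterministic toy encoder with planted sense similarity stands in
for pretrained weights, so the whole pipeline runs offline; any encoder
exposing `tokenize` / `layer_vectors` / `masked_probability` can be
plugged in.

## Worked example

Twelve participants respond to APPEAL; both raters classify 8 responses
as sense 1, 4 as sense 2, and 2 as OTHER:

```r
library(ambinorm)
tal <- tally_sense_assignments(assignments, n_senses = 2)
tal$counts          # 16  8   (each rater's label counts once)
tal$percentages     # 0.667 0.333
dominance_score(tal)
#>   word    top1  top2    p1    p2 score n_responses balanced
#> 1 APPEAL     1     2 0.667 0.333   0.5          24 TRUE
```

Sense 1 holds two thirds of the classified ratings, so its dominance is
(0.667 − 0.333)/0.667 = 0.5 — a fairly balanced word, under the 0.75
cutoff.

A full simulated similarity norming (320 items, 88 raters, two planted
flat raters):

```r
r    <- simulate_rating_study(rating_study_config(seed = 42, n_flat_raters = 2))
excl <- exclude_participants(r$ratings, r$items)
excl$excluded
#>   participant_id reason
#> 1 S001           flat
#> 2 S002           flat
kept <- r$ratings[r$ratings$participant_id %in% excl$kept, ]
st   <- item_statistics(kept, r$items)
condition_statistics(st)$conditions
#>   condition         n_items  mean    sd
#> 1 Homonym                80  1.60 0.339
#> 2 IrregularPolyseme      80  2.60 1.15
#> 3 RegularPolyseme        80  4.78 1.07
#> 4 Unambiguous            80  6.26 0.412
loo_agreement(kept)$summary$mean
#> 0.89
```

Both planted uncooperative raters are caught, the four condition means
recover the configured continuum (Homonym lowest, Unambiguous highest),
and all six pairwise condition contrasts come out significant at
adjusted p < .01. `run_pipeline(run_config(seed = 7))` chains every
stage — simulation, dominance, similarity, encoder metrics, model
comparisons — into one reproducible output directory.

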