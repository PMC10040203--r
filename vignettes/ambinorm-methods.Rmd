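---
title: "Methods: dominance and zeugma-similarity norming of ambiguous words"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance and zeugma-similarity norming of ambiguous words}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambinorm)
```

`ambinorm` implements two norming analyses for lexically ambiguous words
and a pipeline comparing the human norms with contextual-encoder
metrics. This vignette documents the statistical model behind each
stage, the tunable parameters, the synthetic-data generator that the
tests run against, and the design choices made where the methods left
room for them.

## 1. Dominance from classified free associates

Each participant supplies two free associates per word; two raters
independently classify every response as matching one of the word's 2–5
candidate senses or as OTHER (multiple, undifferentiable, or no sense).
The tally counts **ratings**, not responses: a response labeled by both
raters contributes two ratings, and when the raters disagree, each label
is credited to its own sense. OTHER ratings enter neither the counts nor
the denominator, which is the total number of ratings aligned with any
selected sense. With `p1 >= p2` the top-two sense proportions, the
dominance score is

$$D = \frac{p_1 - p_2}{p_1} \in [0, 1],$$

zero for perfectly balanced meanings, one when the runner-up sense drew
no classified associates. Words whose responses are all OTHER raise an
explicit empty-tally condition and are skipped, mirroring the practice
of rejecting unratable items. The balance flag uses the conventional
cutoff `D <= 0.75`, exposed as a parameter.

Decisions where the procedure is underdetermined:

* **Ties for the top two senses** break toward the lower sense index.
  `D` itself is unaffected (tied `p1 = p2` gives `D = 0`; tied
  runners-up give equal `D`).
* **A sense label from one rater plus OTHER from the other** counts the
  sense and drops the OTHER; the consensus resolution
  (`resolve_consensus_labels()`) likewise lets a lone sense label stand.
  The alternative — letting OTHER veto the sense — would discard
  information the rater provided; the choice matters only for words with
  high OTHER rates and is easy to audit from the assignment table.
* Interrater **coverage** is the fraction of responses labeled by both
  raters; **consistency** is the fraction of both-labeled responses
  whose labels are the same non-OTHER sense.

## 2. Similarity from zeugma ratings

Items are single sentences coercing both meanings of the target onto one
anaphoric referent, rated 1 ("meanings not similar at all") to 7 ("the
very same meaning") under four conditions: Homonym, IrregularPolyseme,
RegularPolyseme, Unambiguous.

* **Participant exclusion.** The flatness rule excludes a rater whose
  Homonym and Unambiguous condition means differ by at most 0.5 on the
  7-point scale. With only two values, the "spread between the two
  anchor-condition means" is read as their absolute difference — a
  literal variance of two numbers would halve the scale and make the
  printed 0.5 threshold inconsistent with the rule's purpose of catching
  raters insensitive to item type. Incompleteness (fraction of items
  rated, default threshold 0.8) and missing anchor data are distinct
  reason codes, since they call for different handling downstream.
* **Item statistics** use the sample SD (n − 1) and SEM = SD/√n.
* **Condition statistics** are computed across item means, not pooled
  ratings: the published across-condition SDs (e.g. 0.44 for
  unambiguous items) sit far below within-item rating SDs (around 0.9–1.6),
  so only the across-item reading is coherent. Pairwise comparisons are
  Welch (unequal-variance) t tests on item means — the method is stated
  only as "t tests", and Welch is the safer default given the visibly
  unequal condition variances — Bonferroni-adjusted for the six pairs,
  flagged at α = 0.01.
* **Leave-one-out agreement.** For each rater, Spearman ρ (average
  ranks for ties) between their ratings and the mean rating of the
  remaining raters over shared items. Raters with fewer than 3 usable
  items, or with constant ratings (undefined ρ), are excluded from the
  summary with a warning rather than imputed.

## 3. Encoder metrics

For each zeugma sentence the encoder provides per-layer, per-subtoken
vectors and a masked-token probability. A word split into several
subword pieces is represented by the unweighted mean of the piece
vectors covering its character span (0-based, half-open offsets). The
two metrics are the per-layer cosine distance
`1 − u·v/(|u||v|)` between the target and anaphor span embeddings, and
the anaphor surprisal `s = −log p` with the anaphor masked. Natural
logarithm is the default (the base is an arbitrary unit choice and is
recorded in the run metadata; base 2 gives bits, with
`s_e = ln 2 · s_2`). Items whose anaphoric expression contains
whitespace ("a lot") are excluded before surprisal is defined; the
filter is idempotent and reports its removal count. Layer-wise Pearson
correlations between cosine distance and human item means carry 95%
confidence intervals from the Fisher z transform. Layers are indexed
1..L (contextual layers only; a static layer 0 is not part of the toy
encoder's contract).

## 4. Nested mixed-model comparisons

Two families of likelihood-ratio tests, each Bonferroni-corrected for
the two encoder metrics:

1. `metric ~ condition + (1 | anaphor)` against the intercept-only
   model, for surprisal and for final-layer cosine distance (condition
   contributes 3 parameters);
2. `mean_similarity ~ condition + metric + (1 | anaphor)` against the
   model omitting the metric (1 parameter).

All fits use **maximum likelihood, not REML**: REML likelihoods are not
comparable across fixed-effect structures, so ML is forced for every fit
entering a test. Condition uses R's default treatment coding, so the
intercept estimates the alphabetically first level (Homonym). Singular
fits (zero estimated anaphor variance) are retained with a warning — in
that limit the fixed effects collapse onto ordinary least squares, which
the tests verify to 1e-4. χ² is floored at zero against optimizer noise
(tolerance 1e-6), and comparing a model with itself is treated as the
degenerate case χ² = 0, df = 0, p = 1. Both directions of the
"similarity beyond condition" question (dropping the metric, and
dropping condition) can be run; the shipped family reports the dropped
metric, and `fit_mixed_model`/`likelihood_ratio_test` compose freely for
the other direction.

## 5. The synthetic-data generator

The generator replaces the human studies so that every stage is testable
offline. What it emulates, and the defaults that define the simulated
study conditions:

* **Associate studies.** Responses are symbolic tokens whose latent
  sense is an i.i.d. draw from the word's sense mixture. Rater 1 labels
  every response with its true sense; rater 2 labels it with probability
  0.757 (the observed both-rater coverage) and matches rater 1 with
  probability 0.949 (the observed consistency), otherwise picking
  uniformly among the word's other senses — the aggregate statistics are
  all the data constrain, so the disagreement model is the simplest one
  consistent with them. When no mixture is supplied, each word gets two
  senses with the dominant proportion uniform on (0.5, 1) — a
  maximally uninformative prior over how biased a word can be. It
  implies a dominance distribution with mean 2 − 2 ln 2 ≈ 0.614,
  SD ≈ 0.28 and P(D ≤ 0.75) = 0.6, closely matching the published
  dominance summaries (mean 0.61, SD 0.27, 63.8% at the cutoff), which
  is why the acceptance checks can recompute those summaries from the
  generator at study scale (547 words × 106 responses).
* **Rating studies.** Item true means are drawn per condition from
  Normal(M, SD) with the published condition statistics
  (M = 1.63/2.57/4.96/6.28, SD = 0.33/1.14/1.27/0.44) and clamped to
  [1, 7]; each rating is a Gaussian draw around the item mean, rounded
  and clamped to the integer scale. Rounding onto a bounded scale pulls
  expectations toward the middle, so the latent Gaussian mean is
  calibrated (by inverting the expectation of the discretized
  distribution) so that the *observed* rating mean equals the item's
  true mean; without this, condition means near the scale ends would be
  biased by ~0.2 and parameter-recovery checks would be testing the
  bias, not the pipeline. The within-item rating SD (default 1.2) is a
  package choice of the order of the within-item SDs printed for example
  items; it is not a published value. Planted flat raters give one
  constant rating (drawn once from 3–5) to every item, guaranteeing they
  trip the flatness rule.
* **Zeugma items** are template sentences over symbolic words with one
  target span and one anaphor span; a configurable fraction receives the
  multiword anaphor "a lot", single-word anaphors vary ("one", "it",
  "that", "some", "them") so the anaphor grouping factor has several
  levels, and every eighth target is long enough to be split by the
  subword tokenizer so span averaging is exercised. Each item carries a
  planted `true_similarity` in [0, 1], drawn from the condition's rating
  distribution rescaled from [1, 7]; passing the items to
  `simulate_rating_study()` ties the human ratings to the same ground
  truth the encoder sees.
* **The toy encoder** is a deterministic test double, not a trained
  model. Token vectors are seeded unit Gaussian directions hashed from
  (token, layer, seed); for a known item, the anaphor vector at layer
  `l` is the spherical interpolation
  `cos(φ)·t + sin(φ)·u` with `φ = (1 − blend)·(π/2)·(l/L)`, `t` the
  target span direction and `u` a planted orthogonal distractor. Cosine
  distance is therefore exactly `1 − cos(φ)`: strictly decreasing in the
  planted similarity, zero at blend 1, with the widest dynamic range —
  hence the strongest correlation with human means — at the final layer.
  The masked anaphor probability is `0.02 + 0.96·blend`. Defaults are 12
  layers × 768 dimensions, the geometry of the base-size bidirectional
  transformer the metrics are designed for; tests use smaller encoders,
  since the contracts are dimension-free.

Every generator draws from its own RNG substream derived from
(seed, stage tag), so adding one generator call never perturbs another,
and all outputs are byte-reproducible for a fixed config.

**What passing tests do and do not show.** The generator matches the
designs' first and second moments, the exclusion structure, and the
planted monotone link between sense similarity, ratings, and encoder
geometry. It does not model real free-association semantics (responses
are symbolic), rater biases that correlate across items, skewed or
bimodal rating distributions within items, or the weak, noisy
similarity–embedding relation of a real pretrained model (the planted
correlations are near −1; real ones are closer to −0.2 to −0.35). Green
tests certify the analysis code, not claims about human raters or any
particular language model.

## 6. Numerical choices and degenerate inputs

* Dominance requires `p1 > 0`; `p2 = 0` legitimately yields `D = 1`.
* SEM·√n = SD holds exactly; items with n < 2 report undefined SD/SEM.
* Cosine distance clips floating-point excursions to [0, 2] and refuses
  zero-norm vectors; surprisal refuses probabilities outside (0, 1].
* Probability vectors must sum to 1 within 1e-12.
* Character spans are 0-based half-open everywhere; casing is preserved
  in stored sentences and lowercasing is delegated to the encoder.
* TSV is used instead of CSV (sentences contain commas); UTF-8 with BOM
  and CRLF tolerated on input. Reads reject malformed rows with row
  numbers and abort above a configurable 5% malformed fraction.
* With a constant response, the Gaussian ML log-likelihood diverges
  (+Inf); fits still return zero coefficients, and such responses are
  not meaningful LRT inputs.

## 7. Problem sizes used by the test suite

Unit tests run on handmade fixtures of a few rows. The study-scale
checks use the full simulated designs: 320 items × 88 raters for the
rating study and 547 words × 53 participants × 2 responses for the
dominance study. The null-calibration check for the likelihood-ratio
test uses 1000 simulated datasets of 50 observations in 10 anaphor
groups, verifying a type-I error near 0.05 and approximately uniform
p-values. Statistical recovery assertions use 3-standard-error
tolerances around the configured values.

## 8. Interfaces and limitations

The package's surface is its functions: generators, the four analysis
stages, and `run_pipeline()`, which chains them into one immutable,
manifest-stamped output directory (`simulate → dominance → similarity →
nlm → compare`) — the reproducible-run entry point scripted usage should
call. An adapter for a real pretrained encoder only needs to implement
`tokenize`, `layer_vectors`, and `masked_probability`; no such adapter
ships here because the package deliberately carries no model weights.
Known limitations: the mixed models support a single random intercept
(no random slopes or crossed effects); multi-subtoken anaphors are
excluded rather than scored; the masked probability is assumed to be
normalized over the encoder's full vocabulary; and the dominance module
classifies nothing itself — it presumes human (or upstream) sense
assignments.
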