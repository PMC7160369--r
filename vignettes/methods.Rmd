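---
title: "Methods: cluster/switch segmentation, foraging-timing features, and balanced pair-out validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster/switch segmentation, foraging-timing features, and balanced pair-out validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfforage)
```

This vignette documents the scientific and numerical decisions behind
`vfforage`: what the pipeline computes, which choices were genuinely open and
how they were settled, and what the synthetic cohorts do and do not
demonstrate.

## The retrieval model

A timed category-fluency response is modelled as a two-part memory search:
retrieval *within* a semantic cluster of related items, and *switches*
between clusters. The foraging analogy (marginal value theorem) supplies the
hypothesis that discriminates clinical groups: an efficient searcher leaves
a depleting cluster when the expected gain elsewhere exceeds the local gain,
so for a well-timed switch the cost of the transition (switching duration,
SD) is commensurate with the payoff once arrived (intra-cluster retrieval
time, ICRT). Their per-switch mismatch, `OSR = |SD − ICRT|`, is the central
timing feature; impaired search shows larger mismatches and lower word
production.

Two semantic representations drive the same-cluster decision:

* **Table rule** ("Troyer"): two names are related iff their curated
  subcategory sets intersect. Names carry 1–4 subcategory labels; the
  loader rejects tables violating this contract.
* **Embedding rule** ("ESA"): two adjacent names are related iff the cosine
  similarity of their word vectors is at or above a threshold. Any
  word2vec-text-format embedding file is accepted; the pipeline only ever
  consumes pairwise similarities, not the vectors' provenance.

Segmentation is a greedy left-to-right scan over *adjacent pairs only*: the
sequence of similarities `d(W_{i−1}, W_i)` fully determines clusters and
switches. Multi-item chain rules (e.g. re-attaching a word to an earlier
cluster) are deliberately not modelled — the adjacent-pair rule is what the
timing features are defined on, and it keeps the switch set identical
between the count and timing blocks.

Two conventions required a decision:

* **Similarity vs distance.** The literature mixes "cosine distance" and
  "cosine similarity" for this quantity. We use *similarity* throughout:
  higher = more related, switch ⇔ similarity < threshold. This orientation
  is the only one consistent with the worked seven-word example the package
  reproduces (`make_worked_example()`).
* **Boundary ties.** A pair exactly at the threshold stays in the same
  cluster (a pair is "different" only strictly below the threshold).

## Subject-adaptive threshold

With a fixed threshold, one global value must suit every subject's
similarity scale. The adaptive mode instead min–max normalizes the
response's adjacent-pair similarities to [0, 1] and sets the threshold at a
fraction (default 0.75) of their normalized mean; the comparison then
happens on the normalized scale. Consequences worth knowing:

* The rule is invariant to affine transforms of the raw similarity scale
  (tested property), so embeddings with different dynamic ranges are
  comparable.
* "All word pairs of the response" is read as *successive* pairs; a
  `scope = "all"` option normalizes over all C(n, 2) pairwise similarities
  instead for sensitivity analysis.
* If every similarity in a response is identical the normalization is
  degenerate; the response falls back to a single cluster with a warning
  rather than an arbitrary split.
* `sweep_threshold()` traverses fractions 0.50–1.00 in 0.05 steps (11
  settings) and reports one cross-validated AUC per setting.

## Timestamp normalization

Responses contain fillers and examiner speech with real duration. After
token classification, non-animal tokens are removed by **interval
collapse**: each removed token's duration is subtracted from all later
onsets, as if cut from the tape. The alternative reading of "normalize the
timestamps to the length of the shortened audio" — proportional rescaling —
is available as `time_norm = "fraction"`, but collapse is the default
because it preserves the raw second-scale gaps of the worked example (0.7 s,
0.9 s) while removing interruption-induced inflation, and it conserves
total time exactly (shortened duration + removed duration = original
duration, a tested invariant). Gaps between animal words with no removed
speech between them are untouched, so SD and ICRT are invariant to
interruptions outside the measured span.

Token normalization is entirely local: a lexicon file supplies canonical
singular names, irregular plurals (*hippopotami* → *hippopotamus*, *oxen* →
*ox*) and multiword names (*mountain lion*, *great white shark*), with a
conservative suffix stemmer (`-s`, `-es`, `-ies`) that fires only when the
stem is a known name — so *moose* survives. Multiword names are merged into
one token (onset of the first word, summed durations). The original
analysis resolved unknown names against online dictionaries; we replace
that with static files for reproducibility. Duplicate productions
(perseverations) are kept in the sequence — they are segmented and timed
like any token — and uniqueness is applied only in the unique-word count;
the duplicate count is its own feature. Names the chosen semantic
representation cannot place (not in the table / no embedding) are treated as
non-animal for that run, with a per-subject warning.

## Feature vector

The published 17-item count-feature list contains two literal repetitions
(switch count and mean cluster size appear twice) and two items — "unique
animal words" and "unique words" — that coincide once the sequence has been
normalized to canonical animal names. We therefore emit 15 distinct
count-based columns plus the single-cluster ratio, and 15 timing aggregates
(mean, median, population variance, min, max over present values of SD,
ICRT, OSR). Aggregate conventions:

* Variance/SD are population moments (divide by n): the aggregate describes
  this response, it does not estimate a super-population parameter.
* ICRT is undefined for a switch into a singleton cluster; OSR inherits the
  missingness. Aggregates use present values only, and a response with no
  usable values (e.g. zero switches) gets missing aggregates rather than
  being dropped — imputation is deferred to the classifier, which fills
  cells with the training-fold median so no test information leaks.
* Log word frequency uses the natural log; tokens with zero or missing
  frequency are excluded from that feature with a warning rather than
  producing −∞.

## Classifier and validation

Features are scaled by the robust quantile rule `f(x) = (x − Q1)/(Q3 − Q1)`
**in its published first-quartile form** — centring on Q1, not
the median, so Q1 maps to 0 and Q3 to 1. The conventional median-centred
robust scaler is available via `scaler_center = "median"`. Quantiles use
linear interpolation between order statistics (R type 7); the convention
matters at these sample sizes and is pinned by tests. Constant columns
(zero IQR) are flagged and scaled to 0.

The classifier is a maximum-margin linear SVM. The L2-penalized form is
fitted by libsvm (via e1071). For the L1 penalty — which the best published
configuration uses, and which recursive feature elimination benefits from —
no installed backend fits an L1-penalized SVM, so the package minimizes
`||w||₁ + C Σ max(0, 1 − y f(x))²` (squared hinge, unpenalized intercept)
by accelerated proximal gradient (FISTA, 300 iterations, stopping when the
coefficient change falls below 1e−7). Decision scores are always oriented
so positive favours MCI.

Evaluation uses balanced leave-one-pair-out CV. Open details were settled
as follows:

* **Pairing rule.** Each minority-class (MCI) subject is paired with a
  distinct, uniformly sampled majority-class (CI) subject per repeat; no
  pairing rule is prescribed beyond randomness, and uniform sampling is
  the least-informative choice. With 28/42 subjects every training fold
  holds exactly 27 + 27 (a tested invariant), and per-repeat metrics pool
  the 2 × 28 held-out scores.
* **Where feature selection runs.** Whether recursive elimination ran
  inside each training fold or once per repeat is unstated. The default is
  `rfe = "none"` (explicit feature sets); `"per_repeat"` runs RFECV once on
  the pool per repeat (cheap, slight optimism), `"per_fold"` is strictly
  nested (slow, unbiased). RFECV scores each visited subset by mean inner
  stratified k-fold AUC and returns the best, ties to the smaller subset.
* **Hyperparameters.** Defaults C = 10, L1 (the best published setting);
  `tune = TRUE` grids C ∈ {1e−10, 0.1, 1, 10} × {L1, L2} by inner CV.
* All randomness (pairing, subsampling, inner folds, chance scores) flows
  from one seed; a rerun with the same seed is bit-identical (tested).

AUC is computed by threshold sweep from "everything positive" to
"everything negative", equal to concordant-pair counting with ties at ½
(delegated to pROC and verified against a brute-force oracle).

## A note on the worked example's OSR

The package's `OSR = |SD − ICRT|` gives {0.5, 0.5} on the worked
seven-word response (SD {0.7, 0.9}, ICRT {0.2, 0.4}); the figure caption's
rule and its first value agree with this. Any second value other than 0.5
is arithmetically inconsistent with the definition, so the package reports
the formula's result.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 28 MCI / 42 CI subjects,
60 s responses, group word-production targets Normal(17.3, 4.99) for CI and
Normal(13.3, 4.12) for MCI (the published cohort statistics). Retrieval is
simulated as patch foraging over the category table: cluster lengths 1–4,
intra-cluster gaps log-normal(log 1.2 s, 0.35), switch gaps
log-normal(log 2.0 s, 0.45) for CI, multiplied by `osr_inflation` (default
1.5) for MCI, with a mild linear slowing over the minute. Log-normals were
chosen for positive support and the right skew typical of inter-retrieval
intervals; the published protocol prescribes no distribution (it measured real recordings).
Examiner interruptions (Poisson, mean 1 per response) are inserted as
real-duration token runs that push later speech back, exercising the
trim/renormalize path end to end. Occasional perseverations (p = 0.05)
exercise duplicate handling.

Fixture embeddings give each subcategory an orthonormal centroid direction
and each word the mean of its subcategories' centroids plus isotropic noise,
so within-subcategory cosine similarity exceeds between-subcategory
similarity by construction. The bundled category table is a small synthetic
stand-in (44 names, 8 subcategories) — the published 545-name instrument is
not redistributable — and is labelled as such.

What passing tests on these cohorts show: the pipeline recovers injected
group differences (sign and ordering of `osr_mean`/`sd_mean`, KS
significance at large effect, cross-validated AUC well above chance) and
stays at chance on null cohorts. What they cannot show: performance on real
speech, where disfluencies, alignment error, out-of-lexicon names and
non-log-normal timing all intrude; published AUC values from the original
70-subject audio corpus are not reproducible without that corpus and are
not asserted anywhere in the package.

## Problem sizes and numerical tolerances in the test-suite

The suite checks exact worked-example arithmetic to float precision;
oracle equivalences on exhaustive small inputs (AUC n ≤ 8, KS samples ≤ 6,
segmentation n ≤ 10); and stochastic properties at sizes chosen to keep the
full suite to a few minutes: chance-model AUC with 500 repeats on one 28/42
cohort (expected within 50 ± 2), KS power over 12 seeded cohorts at
`osr_inflation = 2`, and null-cohort AUC averaged over 8 scaled-up (60/90)
cohorts at 12 repeats each, where the per-cohort noise of cross-validated
AUC (several points at n = 70) would otherwise swamp the expectation.
Word-production target recovery uses 200 subjects per group (tolerance
± 1.0 word).

## Known limitations

* The adjacent-pair switch rule ignores the multi-category ambiguity
  resolution of the original table-based protocol; counts can differ from
  a human scorer applying chain rules.
* ICRT (hence OSR) is undefined for singleton clusters; responses dominated
  by singletons carry little timing information and lean on the count
  features.
* The L1 solver uses a squared hinge; coefficients differ slightly from an
  exact-hinge L1 SVM, though selection behaviour (sparsity, ranking) is the
  point of that penalty here.
* `lopo_cv()` with `rfe = "per_repeat"` evaluates selection on the same
  pool it trains on; use `"per_fold"` when unbiased selection matters more
  than runtime.
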