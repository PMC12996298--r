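---
title: "Predicting depression severity from voice-diary transcripts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting depression severity from voice-diary transcripts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depression severity is usually tracked through infrequent clinic visits.
Weekly smartphone voice diaries paired with in-app Beck Depression
Inventory (BDI) self-reports offer a continuous alternative: short
free-speech recordings are transcribed, turned into numeric feature
matrices (sentence embeddings, TF-IDF, timing/lexical statistics, acoustic
descriptors), and regressed onto the BDI sum (0–63; bands 0–13 minimal,
14–19 mild, 20–28 moderate, ≥29 severe). `voicebdi` implements that whole
analysis as a tested pipeline: cohort structure, diary–BDI pairing,
feature construction, participant-grouped nested cross-validation of a
z-score → PCA → SVR pipeline, stacked late fusion, permutation inference,
calibration analysis, linguistic-perturbation ablations, idiographic
change tracking, and an embedding-space topic layer.

Because raw clinical audio and transcripts cannot be redistributed, the
package ships a synthetic cohort generator that emulates the statistical
structure such a study produces, and every downstream stage is exercised
and tested against cohorts whose ground truth is known by construction.
User-supplied data in the documented tabular formats (a diary table with
role-tagged tokens, a BDI item table, one feature matrix per modality) flow
through the identical functions.

## The synthetic cohort generator

`cohort_config()` defaults encode the study conditions the pipeline
assumes:

* **Groups.** 284 participants, 45.1% with an MDD diagnosis.
* **Adherence.** Per-participant diary counts follow a rounded log-normal
  with floor 1 (`meanlog = log 2`, `sdlog = 1.85`), giving median 2 and
  mean ≈ 11 diaries — the heavy right skew of bring-your-own-device
  designs. A two-parameter log-normal is the simplest law that reproduces
  mean ≫ median.
* **Severity.** A latent AR(1) series per participant around group means
  12.1 (MDD) and 3.5 (HC) with stationary SDs 9.36 / 4.29 on the BDI
  scale. The lag-1 coefficient defaults to 0.7; within-person
  autocorrelation of real weekly BDI series is not published for this
  design, so 0.7 is a design choice (weekly mood is strongly but not
  perfectly persistent), not an estimate.
* **BDI records.** Each diary receives a self-report within the ±7-day
  pairing window with probability 0.97, at a uniformly jittered offset of
  up to ±3 days. The sum is `clip(round(latent + N(0, 1.5)), 0, 63)`; the
  21 items (0–3 each) are allocated to match the sum exactly by
  proportional loading with largest-remainder rounding, so
  `sum(items) == sum` holds by construction.
* **Transcripts.** Role-tagged (surface, lemma, role) tokens assembled
  from six theme-specific content lexicons interleaved with a fixed
  function-word inventory. Severity is planted at three linguistic levels
  with independently tunable strength:
  1. *content* — theme log-odds slopes on standardised severity (the
     distress/care theme rises with severity, activity/work themes fall);
  2. *word order* — every sentence opens with a marker bigram
     ("ich habe" canonical vs "habe ich" inverted) whose inversion odds
     fall with severity; a small marker vocabulary keeps this channel
     statistically learnable;
  3. *inflection* — a marked suffix ("-te") on content words whose odds
     rise with severity; a rare neutral "-en" suffix adds inflection
     variety without signal.
  The default content-channel strength is deliberately scaled below the
  planted text-embedding fraction (35%), so that under the default
  conditions the text modality is the strongest single modality and
  TF-IDF — which can only read the content channel — sits between text
  and the audio-like modality, matching the modality ordering the
  emulated design reports. Sex and age are generated (with group-specific
  means matching the cohort table) but carry no signal; they only feed
  the summary table.

One global seed splits into named sub-streams (participants, adherence,
trajectory, timestamps, themes, text, noise), so changing one knob never
reshuffles unrelated draws; `substream_seed()` exposes the same mechanism
to analysis scripts.

## The synthetic embedding provider

Real sentence-embedding models are out of scope; the provider contract
(`embedding_provider()` + `build_modality_matrix()`) replaces them with a
deterministic signed-hashing map. A diary's vector is

$$v = A\,\varphi(\text{tokens}) + \beta\, s\, u + \varepsilon,$$

where φ hashes four feature families into disjoint blocks of the
embedding — unigram surfaces, order-sensitive adjacent bigrams (within
sentence), word-final character trigrams (the inflection carriers), and
function-word patterns — each block L2-normalised and scaled by a block
weight; *u* is a fixed seeded unit direction, *s* the diary's latent
severity, and ε isotropic noise keyed per diary id (rows are a pure
function of diary identity, never of row order). The block structure makes
perturbation bookkeeping exact: within-sentence reordering can only move
the bigram block, vowel masking and interior shuffling the trigram block,
lemmatisation the unigram and trigram blocks.

When a provider carries `target_r2`, the severity-direction noise is
calibrated against the cohort's empirical severity/BDI moments so that a
linear readout along *u* explains the requested fraction of BDI variance.
This is what "a text-like modality encodes 35% of BDI variance" means
operationally; an audio-like modality is the same construction at 5%.
A `speaker_confound` provider instead encodes a per-speaker fingerprint
plus the speaker's *mean* severity — no within-person signal — and exists
to demonstrate the leakage that participant-grouped cross-validation
prevents.

Hash resolution matters: each block has `dim/4` signed buckets, so theme
vocabularies are only separable in embedding space at `dim ≥ 256`
(64 buckets per block); at `dim = 64` collisions fold distinct themes
together. Benchmark experiments, which need only the planted severity
direction, use `dim = 128`; topic experiments use `dim = 256` with
content-weighted blocks (weights 3/0.3/0.3/0.2) and longer transcripts
(150 tokens), because cluster recovery is a geometry problem, not a
regression problem.

## Modelling protocol

All models share one `build_fold_plan()`: five outer folds and three inner
folds grouped by participant, balanced by participant count (diary counts
may differ), seed-deterministic, fingerprinted by `plan_hash` which paired
comparisons enforce. A stratified variant guarantees both diagnostic
groups in every fold for classification. `build_ungrouped_fold_plan()` is
a deliberately broken diary-level mode for the leakage demonstration only.

`fit_eval_single()` runs, per outer fold, a randomized search (default
budget 30 draws; experiments here use 5–10 to stay at desk scale) over the
SVR kernel (RBF/linear), `C` (log-uniform 10⁻²–10³), ε (log-uniform
10⁻³–10), and the PCA dimensionality (grid 2–50, capped per fold),
scored by inner-CV MAE; the winner is refit on the full outer-training
split and evaluated once. Scaler and PCA are learned on training
partitions only; TF-IDF enters as a *builder* refit on the training
diaries of each split so document frequencies never leak. Inner selection
optimises MAE (reported first throughout) — a documented choice, as is
the cap of the linear-kernel `C` at 32: libsvm's linear solver fails to
converge when weak regularisation meets collinear features, and beyond
that point the linear arm is redundant anyway. Zero-support-vector fits
(all targets inside the ε tube) are predicted as the training mean.

`stacked_fusion()` follows stacked generalization: per outer-training
split, each modality's base model is tuned by its own randomized search,
its inner out-of-fold predictions form the meta-feature table, a ridge
meta-learner (unpenalised intercept; penalty from a small grid by
inner-fold CV; base predictions not re-standardised) is fit on it, base
models are refit on the full outer-training split, and metrics come from
the meta-learner's outer-fold predictions. The ridge solve is closed-form
penalised least squares — with two to six meta-features a path algorithm
adds nothing.

Baselines are a mean-prediction dummy regressor and a stratified dummy
classifier. Negative R² is reported as-is. The idiographic analysis
(≥10 paired entries) fits per-person ridge models on embedding-difference
principal components to predict week-to-week BDI change, against a
no-change baseline and a calibrated global model (fit on non-frequent
participants, per-subject offset from the training segment), with
deterioration detection at ΔBDI ≥ 3, 5, 7.

## Inference

Head-to-head comparisons use paired sign-flip permutation tests on
per-fold metric differences: exhaustive enumeration when `2^folds ≤ 4096`
(five folds → all 32 patterns, an exact small-sample null) and sampling
with an add-one correction otherwise; percentile bootstrap CIs (2000
resamples) accompany the mean difference, with Cohen's d_z (plus Cliff's Δ
for MAE) and Cohen's f² for R² contrasts. Label-shuffle tests re-run the
pipeline on permuted targets at a reduced search budget; the default
permutation unit is the participant (whole target blocks swapped between
participants of equal diary count), because diary-level shuffling would
break the within-person correlation the grouped CV is designed to respect
— both units are implemented. Type-I calibration of this test requires
each replicate to be a fresh draw of the whole system (cohort, plan,
features): with a single fixed cohort the observed statistic's position in
its own permutation orbit is a constant, and rejection rates are
meaningless.

Topic–symptom inference uses Spearman's ρ with Fisher-z CIs, Holm–
Bonferroni control within each theme's 21 items, and a Kruskal–Wallis
omnibus for between-theme BDI differences (`stats::kruskal.test`,
tie-corrected).

## Calibration and agreement

On concatenated out-of-fold predictions, residuals are always observed
minus predicted. `calibration_fit()` regresses y on ŷ (ideal: intercept 0,
slope 1); `bland_altman()` reports bias and bias ± 1.96 sd limits;
`proportional_bias()` regresses residuals on pair-wise means. Bootstrap
CIs resample diaries by default — predictions are the stated unit — with a
participant-level cluster bootstrap available because diaries are not
independent.

## Topic layer

Embeddings are L2-normalised (cosine geometry), reduced to five principal
components, and clustered by a density-based algorithm with noise labels:
core points need `min_cluster_size` neighbours (default `max(15, n/100)`)
within a radius set from the k-nearest-neighbour distance distribution.
The package implements this clusterer directly, with nearest-centroid
outlier reassignment (ties to the lower id) and a centroid-softmax
soft-assignment fallback (temperature defaulting to the median
diary–centroid distance), so every diary ends with a dominant topic and a
row-stochastic probability vector. Clusters are consolidated to six themes
by average-linkage agglomeration of centroid cosine distances; keywords
are class-based TF-IDF, `W(t,c) = tf(t,c) · log(1 + A/f(t))`; theme naming
is a human step and stays outside the package — themes carry ids, keyword
lists and representative diaries.

## What the synthetic experiments do and do not show

The generator emulates *structure*: group-level BDI distributions, skewed
adherence, autocorrelated trajectories, severity-linked theme prevalence,
and order/inflection channels with known loadings. Passing tests show the
pipeline recovers planted signal at the planted strength, orders
modalities correctly, blocks speaker leakage, keeps its type-I error, and
degrades under perturbations in the order of the planted loadings. They do
not show that real speech carries this much signal, that real embedding
geometry resembles hashed blocks, or that six themes exist in any real
cohort — the published effect sizes depend on undeposited data and
GPU-scale embedding models and are out of reach by design.

## Problem sizes and numerical choices

Experiments are sized for a single CPU: benchmark properties use 120–250
participants with 2–4 diaries each (the study-scale default of ~11 diaries
per participant is used by the cohort-level analysis scripts, with the
benchmark stage capping heavy contributors at 8 diaries); search budgets
are 4–10 draws per outer fold; the label-shuffle type-I study uses 200
replicates at 99 permutations with the fixed-configuration pipeline; the
Holm FWER null uses 10⁴ replicates. Degenerate inputs are handled
explicitly: zero-variance features scale to SD 1, constant predictions
flag an undefined calibration slope, zero fold differences give p = 1 with
a degenerate CI, all-noise clusterings fall back to a single cluster, and
|ρ| = 1 clamps with a degenerate-CI flag. Ties break deterministically
everywhere (earlier BDI in pairing, lower topic id in reassignment, lower
diary id among representatives).

## Limitations

The 18-statistic timing/lexical inventory is a reconstruction from the
feature families the design names (timing via voice-activity detection,
POS/NER-like counts from role tags, lexical diversity); the vector is
named and versioned so an exact inventory can replace it. Silence
detection operates on amplitude vectors (50 ms RMS windows, 50% overlap,
−30 dBFS threshold, ≥0.5 s) rather than audio containers. POS and lemma
information on synthetic data comes from generator role tags; adapters
accept external annotations for real transcripts. German morphology is
mechanical suffixing, deliberately so — the package's claims are about the
analysis machinery, not about German.
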