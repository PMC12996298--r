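# voicebdi

Predicting continuous depression severity from weekly voice-diary
transcripts: an end-to-end, tested analysis pipeline for digital
phenotyping studies that pair short free-speech recordings with in-app
Beck Depression Inventory (BDI) self-reports.

The scientific core is a multimodal regression benchmark under
participant-grouped nested cross-validation. Each diary yields feature
vectors per modality (sentence-embedding-like vectors, 1–2-gram TF-IDF on
normalised text, 18 timing/lexical statistics, acoustic-like vectors); a
shared z-score → PCA → SVR pipeline predicts the BDI sum *y* ∈ [0, 63]
(severity bands: 0–13 minimal, 14–19 mild, 20–28 moderate, ≥29 severe)
from the BDI completed within ±7 days of the diary. Evaluation uses
GroupKFold by participant (5 outer / 3 inner folds, identical across
models) with randomized hyperparameter search over the SVR kernel, C, ε
and PCA dimensionality; multimodal models use stacked generalization (a
ridge meta-learner on inner out-of-fold base predictions). Inference is
permutation-based — label-shuffle tests against chance, paired sign-flip
tests over folds for head-to-head contrasts (exact enumeration at 5
folds), Cohen's d_z / Cliff's Δ / f² effect sizes — and predictions are
audited by calibration-in-the-large and slope (OLS of y on ŷ),
Bland–Altman bias and 95% limits of agreement (bias ± 1.96·SD of
residuals, residual = observed − predicted), and proportional-bias
regression. Controlled linguistic perturbations (within-sentence word-order
shuffling, lemmatisation, vowel masking, intra-word shuffling, the
function-word skeleton and its content-only complement) quantify which
linguistic levels carry the signal, and an embedding-space topic layer
(density clustering with outlier reassignment and a soft-assignment
fallback, cTF-IDF keywords, six-theme consolidation, Kruskal–Wallis and
Holm-controlled Spearman topic–item correlations) provides the
interpretability layer.

Because clinical audio and transcripts cannot be redistributed, the
package includes a first-class synthetic cohort generator
(`generate_cohort()`) that reproduces the data structure such studies
report — two diagnostic groups with distinct BDI distributions, heavily
right-skewed adherence, AR(1) within-person severity, 21 item scores
consistent with the sum, and theme-structured transcripts with severity
signal planted at the content, word-order and inflection levels — so every
claim the package makes is tested against known ground truth. See
`vignettes/voicebdi-methods.Rmd` for the model, its assumptions and the
design decisions.

## Worked example

```r
library(voicebdi)

co   <- generate_cohort(cohort_config(n_participants = 60, seed = 7,
                                      adherence_log_mean = log(3),
                                      adherence_log_sd = 0.8))
mt   <- modeling_table(co)              # diaries paired with BDI (+/- 7 days)
pr   <- embedding_provider("text", dim = 64, seed = 3, target_r2 = 0.35)
x    <- build_modality_matrix(co, pr, mt$diary_id)
plan <- build_fold_plan(unique(mt$participant_id), seed = 11)
res  <- fit_eval_single(x, mt$bdi_sum, mt$participant_id, plan,
                        search_space(budget = 6), "text")
res
#> text: MAE = 4.03 (0.79), R2 = 0.18 (0.14) over 5 folds
dummy_regressor(mt$bdi_sum, mt$participant_id, plan,
                diary_ids = mt$diary_id)
#> dummy_mean: MAE = 5.27 (0.73), R2 = -0.18 (0.28) over 5 folds
```

The text modality was built to encode 35% of BDI variance; on this small
cohort (60 participants, 258 paired diaries) the grouped out-of-fold fit
recovers MAE 4.03 vs the 5.27 of the mean-prediction dummy, with fold-mean
R² 0.18 — fold noise at this size is large, which is exactly what the
fold SDs in parentheses report. `compare_models(res, dummy)` then gives
the sign-flip p-value and effect sizes for the contrast, and
`calibration_report(res)` the calibration/agreement audit.

The numbered scripts under `analysis/` run the full study workflow at
cohort scale (simulate → benchmark → calibration → perturbations →
topics), each a thin narrative driver over the package functions that
writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_benchmark_models.R
Rscript analysis/03_calibration.R
Rscript analysis/04_perturbations.R
Rscript analysis/05_topics.R
```

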