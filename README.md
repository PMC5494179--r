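# listlearn

A headless, fully testable engine for **digital list-learning assessment of
episodic memory** in the CVLT (California Verbal Learning Test) tradition —
the computational core of a gamified neuropsychological test, with no
rendering or interaction layer.

Verbal list learning is one of the most sensitive behavioral probes of the
episodic-memory decline that marks early mild cognitive impairment (MCI)
and Alzheimer's disease (AD). The paradigm: learn a 16-word list (List A, 4
semantic categories × 4 words) over 3 immediate trials, hear an
interference list (B), recall A after short and long delays with and
without category cues, then complete a 44-item yes/no recognition list (C).
`listlearn` implements:

* **Lexicon handling** — load/validate/write TSV word pools (word,
  category, relative frequency, prototypicality, phonetic key) and
  synthesize realistic pools for testing.
* **List generation** — frequency-matched lists A and B (targets 0.000368
  and 0.0000845 by default; exact meet-in-the-middle search on small
  pools, seeded randomized search with lexicographic tie-breaks on large
  ones), presentation orders free of same-category adjacency, and the
  canonical 44-item recognition list (16 targets / 8 from B / 4 prototypes
  / 8 phonetic neighbours / 8 unrelated).
* **Protocol** — the administration schedule as a state machine over any
  responder, emitting validated, host-invariant event logs in simulated
  time (JSON Lines).
* **Scoring** — the full variable battery: per-trial counts, omissions,
  intrusions, perseverations, learning slope, semantic clustering against
  the chance expectation `sum_k m_k(m_k−1)/r`, serial clustering against
  enumerated/Monte-Carlo baselines, primacy/middle/recency (4/8/4
  regions), proactive (B1 − A1) and retroactive (SDFR − A3) interference,
  recognition hits, typed false positives, discriminability
  `(1 − (misses + FP)/44)·100` and log-linear-corrected d′, and latency
  summaries.
* **Simulation** — a generative behavioral model of HC / MCI / AD recall
  (learning, forgetting, cueing, serial-position boosts, clustering
  tendency, intrusions, perseverations, typed false alarms, lognormal
  latencies) that makes every downstream stage testable.
* **Evaluation** — leave-one-out and repeated stratified holdout
  classification with regularized-linear (pairwise ridge voting),
  random-forest and linear-SVM families; macro precision / F1 /
  sensitivity / specificity; random-forest informative-variable selection;
  correlation matrices; paired pre/post comparison of ordinal
  questionnaire scores with the rate-of-increase statistic
  `(median_post − median_pre)/5 × 100`.

## Worked example

```r
library(listlearn)
library(dplyr)

# 1. A word pool and a frequency-matched list set
lex  <- synth_lexicon(10, 16, seed = 7)
pair <- generate_list_pair(lex, seed = 7)
attr(pair$A, "achieved_frequency")   # 0.0003681172  (target 0.000368)
attr(pair$B, "achieved_frequency")   # 8.446094e-05  (target 0.0000845)
C <- build_recognition_list(pair$A, pair$B, lex, seed = 7)
table(C$item_type)
#>  nonshared_B  phonetic_A  prototype_A  shared_B  target_A  unrelated
#>            4           8            4         4        16          8

# 2. Simulate and score a pilot-scale cohort (8 HC, 3 MCI, 5 AD)
cohort <- score_cohort(simulate_cohort(seed = 42))
bind_cols(cohort$subjects[c("subject_id", "group")],
          cohort$batteries[c("total_A", "discriminability_pct", "d_prime")]) |>
  slice(c(1, 9, 12))
#>   subject_id group total_A discriminability_pct d_prime
#> 1 s01        HC         37                 97.7    3.52
#> 2 s09        MCI        25                 84.1    1.80
#> 3 s12        AD          5                 75.0    1.22
```

`total_A` is the summed correct recall over the three immediate A-trials
(0–48): the healthy control recalls most of the list, the AD subject almost
none. Discriminability combines recognition misses and false positives
over all 44 items; d′ separates true recognition from yea-saying.

```r
# 3. Diagnostic classification, leave-one-out, full features + aux block
features <- build_features(cohort, include_aux = TRUE)
glance(loocv(features, "linear", seed = 42))
#>   scheme model  n_features precision    f1 sensitivity specificity
#> 1 loocv  linear        131         1     1           1           1
```

All 16 simulated subjects are classified correctly — the behavior expected
of well-separated diagnostic groups once the auxiliary break-game feature
block is included. `select_informative(features, fraction = 0.06)` ranks
the most informative variables (random-forest impurity), and
`plot_group_scores()`, `plot_serial_position()` and
`plot_correlation_heatmap()` give the standard views.

## Vignette

`vignettes/assessment-engine.Rmd` documents the model and its assumptions:
the frequency-matching search, the clustering chance expectations, the
simulator's generative equations and group presets, what the synthetic
cohorts do and do not say about real patients, and the numerical design
choices (tie-breaks, degenerate-input conventions, seed derivation).
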