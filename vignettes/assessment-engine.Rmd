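---
title: "A headless engine for digital list-learning assessment of episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A headless engine for digital list-learning assessment of episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(listlearn)
library(dplyr)
```

## The problem

Verbal list-learning tests in the California Verbal Learning Test (CVLT)
tradition are among the most sensitive instruments for detecting the episodic
memory decline that marks early mild cognitive impairment (MCI) and
Alzheimer's disease (AD). A subject learns a 16-word list drawn from 4
semantic categories over repeated trials, is exposed to an interference
list, recalls under short and long delays with and without category cues,
and finally completes a 44-item yes/no recognition test. The variables
extracted — learning rate, clustering strategies, serial-position effects,
interference, recognition discriminability, error profiles — form a rich
behavioral signature of memory function.

Gamified, computer-administered versions of this paradigm promise
standardized administration, precise latency capture, and freshly generated
stimulus lists that defeat practice effects. `listlearn` implements the full
computational core such a digital assessment needs, with no rendering or
interaction layer: stimulus-list generation, the administration protocol as
a state machine, automatic scoring, a behavioral cohort simulator, and the
psychometric validation pipeline (classification, variable selection,
correlation, pre/post comparison).

## Stimulus-list generation

Lists are drawn from a *lexicon*: a table of words with semantic category,
relative corpus usage frequency, a prototypicality flag, and a phonetic key.
List A (main) and List B (interference) each take 4 words from each of 4
categories, sharing exactly 2 categories, with disjoint word sets. The
defining constraint is *frequency matching*: each list's mean relative
frequency must approximate a target (defaults 0.000368 for A and 0.0000845
for B, the reference values of the original paradigm) within a relative
tolerance (default 0.15, comfortably containing the deviations the original
lists themselves exhibit, roughly 1%–13%).

The selection minimises the absolute deviation of the 16-item mean from the
target. For pools up to a few hundred 4-subsets per category the search is
exact: 4-subset sums are enumerated per category and combined
meet-in-the-middle. Beyond that a seeded randomized search with a 5,000
candidate budget is used; ties are always broken lexicographically by word
set, so generation is reproducible. If the optimum still misses the
tolerance, generation fails with an infeasibility error that reports the
best achievable deviation.

Presentation order is a uniform draw over permutations with **no two
adjacent same-category items** (rejection sampling). The paradigm's
clustering scores compare recall order against presentation order; a
pre-clustered presentation would make them uninterpretable. This constraint
is a design interpretation (the source paradigm integrates objects into a
virtual walk and does not state an ordering rule).

The 44-item recognition list follows the classical recipe: all 16 A-words
(the only "yes" items), 2 B-words from each shared and each B-exclusive
category (8 total), one highest-frequency prototypical word per A-category
from outside both lists (4), 8 phonetic neighbours of A-words, and 8 words
with no category or phonetic relation to either list. We read the published
composition rule ("2 from each common category, and 2 from the rest") as 2
per category in both cases, the only reading consistent with the canonical
44-item total.

Phonetic relation is operationalized as *identical phonetic key*. The
synthetic lexicon assigns short consonant-skeleton keys to cross-category
word triples, guaranteeing every word at least one phonetic neighbour in
another category while leaving enough key-unrelated words for the
recognition list's unrelated pool. Synthetic frequencies follow a
per-category Zipf ladder (`freq_scale * rank^-1.3`, rank permuted within
category, times lognormal jitter with sigma 0.15). Giving every category
the same frequency ladder is deliberate: it makes both list targets
reachable for any category assignment, so feasibility never depends on
which categories the seed happens to choose — a property a real corpus
approximates across common categories and a list generator must be able to
rely on.

## The administration protocol

The default schedule is: 3 immediate free-recall trials of A, 1 of B,
short-delay free then cued recall of A, a 15-minute break, long-delay free
then cued recall of A, and recognition. The printed protocol table we
follow shows a duplicated immediate-recall row where the classical test has
short-delay recall; we adopt the canonical order (short-delay free, then
cued) and keep the schedule fully configurable, so the literal reading is
also expressible. Cues in cued phases are the four A-category labels.

`administer()` walks the schedule over any *responder* — the simulator, or
an adapter for real input — in simulated time: stimuli advance the clock by
a fixed cadence (2 s/item), responses by their latencies, the break by its
nominal duration. Logs are therefore identical across hosts. Unknown
response tokens are recorded verbatim and only become intrusions at scoring
time. `validate_log()` reports (never raises) ordering, containment and
protocol violations.

## Scoring

All scores are pure functions of the log. Per recall phase: distinct
on-list words count once toward `correct`; repeats of recalled words are
perseverations; off-list responses are intrusions (with multiplicity).
Learning slope is the OLS slope of correct counts on trial number.

Clustering scores compare observed adjacencies with their chance
expectation under a uniform permutation of the recalled items, and report
the difference (observed − expected), which remains well-defined at the low
recall counts typical of impaired subjects:

* **Semantic**: expected adjacent same-category pairs is
  $\sum_k m_k (m_k - 1) / r$ for $m_k$ recalls in category $k$ of $r$
  total — the classical chance-expectation baseline.
* **Serial**: expected forward transitions (position $p$ followed by
  $p + 1$) computed by exhaustive enumeration for $r \le 7$ and by seeded
  Monte Carlo (10,000 permutations) beyond.

Serial-position percentages use the 4/8/4 (25/50/25) region convention
over pooled A-trial recalls. Proactive interference is B1 − A1;
retroactive is short-delay free recall − A3. Recognition discriminability
is $(1 - (\text{misses} + \text{false positives})/44) \times 100$; d′ uses
the log-linear correction (0.5 per cell, 1 per denominator) because hit and
false-alarm rates of 0 or 1 are routine at 16 targets and 28 distractors.
With no recalls the serial-position percentages are undefined and flagged
degenerate rather than imputed.

The exact variable list of the source battery is not public; the battery
here implements the union of the variables named in its description
(per-trial counts, omissions, intrusions, perseverations, both clustering
families per free-recall phase, serial-position effects, interference,
recognition scores) plus per-phase latency summaries, under a stable
documented column schema.

## The behavioral simulator

The simulator is a *behavioral surrogate*, not a cognitive process model:
its purpose is to generate sessions whose scored signatures reproduce the
qualitative clinical structure (HC > MCI > AD in recall, learning,
retention and recognition; the reverse in intrusions and false alarms;
false-alarm rates ordered shared-category > prototype > phonetic >
unrelated). Item recall in trial $t$ at delay $d$ is Bernoulli with
probability

$$\mathrm{clip}\big(p_\text{base} + \lambda (t-1) + b_\text{prim} + b_\text{rec} + b_\text{cue}\big)\cdot \rho^d$$

with group presets $p_\text{base}$ = 0.45/0.30/0.15, learning rate
$\lambda$ = 0.15/0.07/0.02 and retention $\rho$ = 0.90/0.65/0.35 for
HC/MCI/AD, intrusion rates 0.3/1.0/2.0 per phase (Poisson, 70% drawn from
the other list), recognition hit probabilities 0.95/0.80/0.60, and
per-type false-alarm probabilities. Output order mixes category-blocked and
uniform order via the clustering tendency κ. Latencies are lognormal.

Within-group standard deviations are deliberately small (e.g. 0.03 on
$p_\text{base}$), so adjacent groups sit roughly 4–5 within-group standard
deviations apart: the default presets describe clearly separated clinical
prototypes, the regime in which the reference validation reports ceiling
classification. The auxiliary feature block — a surrogate for two break
mini-games whose variables are described only as improving classification —
is 12 features equal to a latent group ability (means +2/0/−2, sd 0.25)
plus Gaussian noise (sd 0.3). These are documented defaults of the
surrogate, all overridable; they are not estimates from human data, and
passing tests under them demonstrates the pipeline's correctness and the
separability regime, not performance on real patients. Real cohorts have
heavier overlap, comorbidity and measurement noise than this generator
produces.

Each subject runs on an RNG substream derived from the master seed and
subject index, and receives freshly generated lists (mirroring a fresh
collection per session), so cohorts are reproducible and insertion-order
independent.

## Validation pipeline

Features are one row per subject: the flattened battery, ordinal
demographics, and optionally the auxiliary block; degenerate scores are
explicit missing values, median-imputed inside the model fitters.

Three model families are exposed, mirroring common practice in small
clinical samples:

* **linear** — regularized logistic models (ridge, glmnet, λ = 0.1) with
  *pairwise one-vs-one voting*. With ordered diagnostic groups nearly every
  feature is monotone across HC > MCI > AD, so the middle class sits on the
  segment between the outer centroids and no single linear score can
  isolate it one-vs-rest; every pairwise boundary, by contrast, is cleanly
  linear. This is the same multiclass construction libsvm uses.
* **forest** — a seeded `ranger` ensemble (500 trees), also the engine for
  impurity-based informative-variable selection.
* **svm** — a linear-kernel maximum-margin classifier (`e1071`).

All families use class-balanced weights: at pilot scale (8/3/5) the
minority class is otherwise squeezed out of the decision rule. Evaluation
schemes are stratified repeated holdout (seeded, redrawing splits that
leave a class out of training) and leave-one-out cross-validation; metrics
are the four ratios precision, F1, sensitivity and specificity, computed
one-vs-rest per class and macro-averaged (the 3-class averaging convention
is unstated in the source and chosen here). Zero-denominator cells return
0 with a degenerate flag rather than erroring, since tiny folds hit them
routinely.

The printed metric equations of the source use a minus sign where a
division is required (e.g. "P = TP − (TP + FP)", which would be negative);
the ratio reading is the only one consistent with reported values in
[0, 1] and is adopted throughout.

`paired_pre_post()` reproduces the pre/post questionnaire analysis: the
rate of increase is the median shift as a percentage of the 5-point scale,
$(\tilde{x}_\text{post} - \tilde{x}_\text{pre})/5 \times 100$ — the only
definition reproducing the published worked values (medians 1 → 3 giving
40%, 3 → 3.5 giving 10%) — alongside a paired t-test.

## Numerical and design choices

* Seeds are threaded explicitly everywhere; substreams are derived as
  `(48271 s + 7919 i) mod (2^31 - 1)` so nested stages never share streams.
* Frequency-match ties are broken lexicographically by sorted word set.
* Rejection sampling for presentation order has a 10,000-attempt budget; a
  category holding more than half the items is rejected immediately
  (pigeonhole: no adjacency-free order exists).
* Exact serial-clustering baselines enumerate at most 7! permutations; the
  Monte Carlo fallback is seeded and vectorized.
* Cohort list generation retries on infeasible or capacity-starved draws
  with derived seeds (up to 10 attempts) rather than failing a whole
  cohort.
* Problem sizes in the test-suite: distributional properties use one
  balanced 36-subject cohort and 40-session comparisons; classification
  checks use the 16-subject pilot-scale cohort; enumeration oracles cap at
  r = 7. These sizes give stable checks at interactive run times.

## Known limitations

* The simulator's independence assumptions (item-wise Bernoulli recall,
  feature-wise Gaussian aux block) understate the correlation structure of
  real behavior.
* No normative standardization (z-scores against population norms) is
  provided; the source defers a normative study.
* "Response to inhibition" is not modelled as a separate variable beyond
  the interference scores.
* Phonetic relation is a string-key equality, not a phonological model of
  any specific language.
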