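---
title: "Supervised attribute clustering ensembles: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised attribute clustering ensembles: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacens)
```

## The problem

Expression-based sample classification works with matrices of a few dozen to
a few hundred samples over thousands of genes. Three pathologies dominate:
the feature space dwarfs the sample count, only a handful of genes carry
class signal, and class sizes are often badly imbalanced. `sacens` attacks
all three at once with a single ensemble construction:

1. **Class-balanced bootstrapping.** `D` replicates of the training set are
   drawn with replacement; within each replicate every minority class is
   topped up by random replication of its drawn members until all class
   cardinalities match the majority. Each replicate is therefore at least as
   large as the original data and exactly balanced.
2. **Multi-filter screening.** On every replicate, seven filter statistics
   (Fisher score, Welch t, chi-square, mutual information, Pearson
   correlation against the class indicator, signal-to-noise ratio, Relief-F)
   each nominate their top `P` genes. Different filters respond to different
   signal shapes, which is what makes the downstream base learners diverse.
3. **Supervised attribute clustering (SAC).** Each filter's `P`-gene subset
   is partitioned greedily: the highest-scoring gene seeds a cluster and a
   running representative `R`; every remaining gene `g`, visited in
   descending score order, is tried both ways — `R + g` and `R - g` — and
   absorbed (with its sign) only when the better of the two strictly
   increases the filter score of `R`. The sign-flip arm is the mechanism
   that lets *negatively* co-expressed genes reinforce rather than cancel
   the class signal. After the pass, the representative is the signed mean
   `R / count` and is re-scored; the `Q` strongest representatives become
   the features of a reduced sub-dataset.
4. **Ensemble.** One base learner (naive Bayes, k-NN, Gini decision tree or
   RBF SVM — one type per run) is trained per reduced sub-dataset, giving
   `D x |filters|` models that predict by unweighted majority vote.
5. **Ranking.** A gene scores one point for every reduced sub-dataset whose
   selected clusters contain it; the occurrence count is a stability-style
   importance measure for biomarker shortlists.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `D` | 10 | bootstrap replicates; accuracy is flat from ~10 upward, so 10 is the default |
| `P` | 200 | genes kept per filter; typical useful range 100–500 for datasets of a few thousand genes |
| `Q` | 3 | representatives kept per sub-dataset; 1–3 already carries most of the signal |
| `filters` | all seven | drop filters to trade diversity for speed |
| `learner` | `knn` (k = 5) | k in 3–7 is sensible; `nb`, `dt` (Gini), `svm` (RBF) available |
| `bins` | `max(2, ceiling(log2(U)) + 1)` | chi-square/MI discretisation, recomputed per scored vector |
| `relief_k` | `min(10, min class size - 1)` | Relief-F neighbours per class |

All values live in a [run_config()] object; the command-line interface
accepts the same fields from YAML/JSON.

## Numerical and design choices

* **Filter forms.** The canonical definitions are used: multi-class Fisher
  score `sum_j n_j (mu_j - mu)^2 / sum_j n_j sigma_j^2`; Welch t
  `|mu_1 - mu_2| / sqrt(sigma_1^2/n_1 + sigma_2^2/n_2)`; Pearson r of the
  feature against the 0/1 class indicator; SNR
  `|mu_1 - mu_2| / (sigma_1 + sigma_2)`; chi-square and mutual information
  (bits) on discretised features; Relief-F per Kononenko's formulation.
  Population (divide-by-n) standard deviations are used throughout, fixed
  for determinism. Signed statistics return absolute values: an
  anti-correlated gene is maximally informative, and direction is handled by
  the sign-flip merge instead.
* **Discretisation.** Equal-frequency binning on ranks (ties broken by
  position), recomputed for every scored vector, so augmented
  representatives are re-binned and the chi-square/MI scores are invariant
  under strictly monotone transforms. A constant vector carries no
  information and scores 0 by convention for every filter.
* **Zero-denominator guards.** Variance-type denominators branch on the
  exact zero instead of adding an epsilon: constant features score 0, and a
  degenerate separated-but-variance-free feature gets a large finite score
  (`num / 1e-12`). An additive epsilon would silently break exact scale
  invariance, which the strict-improvement merge comparisons rely on (a
  duplicated seed must tie, never win).
* **Relief-F.** The native multivariate form (Manhattan distance over
  min-max-normalised genes, all instances used, neighbour counts degrading
  gracefully in small classes) scores whole datasets. Inside SAC, augmented
  representatives are single vectors, so they are scored by the same weight
  formula in the 1-D space of that vector. Relief weights can be negative;
  scores are clamped at zero so that "larger = more relevant" holds
  uniformly across filters.
* **SAC tie rules.** The seed is the maximum-score gene, ties to the lowest
  gene index. The candidate pass is a single frozen, score-descending
  snapshot per cluster (no re-scanning after `R` changes, matching the
  single-pass growth procedure). `TR+` wins score ties against `TR-`;
  acceptance requires *strictly* greater score, which in particular rejects
  exact duplicates of the seed (scale-invariant statistics are unchanged by
  `R -> 2R`). The production implementation evaluates all remaining
  candidates against the current representative in one vectorised batch and
  rescans from the first acceptance; this is arithmetic-identical to the
  literal gene-at-a-time loop, and the test suite verifies exact agreement
  (members, signs, counts, representative vectors) against an independent
  sequential transcription on hundreds of random instances.
* **Q-selection.** Representatives are compared on their re-scored, divided
  vectors. For scale-invariant filters this equals the pre-division score;
  it differs only for Relief-F, where the divided vector is the one actually
  used downstream, so its score is the honest ranking key.
* **Projection of unseen samples.** A reduced sub-dataset maps any sample to
  `Q` features by the signed mean `(sum_i sign_i x[gene_i]) / count` — the
  unique linear map consistent with how representatives were built from
  training profiles.
* **Voting ties.** Broken deterministically toward the label appearing
  first in the training data, preferring reproducibility over randomised
  ties.
* **Evaluation without leakage.** By default every cross-validation fold
  re-runs the complete pipeline (bootstraps, filters, SAC, learners) on its
  training portion only. A `feature_selection = "once"` switch selects
  features a single time on the full data before cross-validating the
  learners; it is provided because published accuracies in this family of
  methods do not always state which protocol was used, but the no-leakage
  protocol is the default and the only one we recommend.
* **Oversampling source.** Minority top-up replicates indices already drawn
  into the replicate (default), with a `"parent"` switch to draw from the
  full minority pool instead.
* **Seeds.** One master seed; child seeds are `master + index` (replicates,
  folds, repeated splits). SAC itself contains no randomness.

## The synthetic generator

There is no public fixture bundled with the package; all tests run on
seeded synthetic data from [generate_expression()]. An informative gene in
class `c` is
`sign_g * (delta * mu_c + sqrt(rho) * f_s) * noise_sd + sqrt(1 - rho) * e`
with equally spaced class offsets `mu_c`, a shared per-sample latent factor
`f_s` inducing pairwise correlation `rho` inside the signal block (negative
between opposite-sign genes), and Gaussian noise elsewhere. This is the
minimal structure that exercises every bespoke mechanism: imbalance
(oversampling), anti-correlation (the `TR-` path), redundancy (clustering)
and noise (filtering).

The frozen reference fixture ([default_fixture()]) has 60 samples (40/20),
1000 genes, 20 informative (half anti-correlated), effect size 3 SD, block
correlation 0.7, unit noise. The generator does **not** emulate microarray
technical artefacts (probe saturation, spatial effects, heavy-tailed or
count-distributed noise, batch structure), so passing tests demonstrate the
mechanics of the method, not performance on any particular real platform.

## Problem sizes used in the checks

The test-suite and the acceptance script run, as the package's chosen
reference workload: clustering-oracle comparisons on 200 random instances
(U <= 12, V <= 8, all seven filters), 500 randomised refinement runs,
100-dataset balance sweeps, and one end-to-end tenfold cross-validation of
the full configuration (D = 10, P = 100, Q = 3, k-NN) on the frozen
60 x 1000 fixture, which also yields the occurrence ranking whose top 20
genes are compared against the planted truth.

## Known limitations

* Greedy single-pass clustering can absorb noise genes that improve the
  training-set score by chance, especially at small sample sizes; the
  occurrence ranking of a strongly selected noise gene can then rival weak
  informative genes. The ensemble vote is robust to this, the ranking less
  so — treat shortlists as candidates, not verdicts.
* AUC is defined for two-class problems only (vote fractions as scores);
  multi-class runs report the confusion matrix instead.
* Relief-F scores depend on all genes jointly; its column in the ranking is
  therefore not invariant to adding or removing unrelated genes, unlike the
  six univariate filters.
* k-NN stores its training projection; model directories grow with `D`,
  `|filters|` and the replicate size.
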