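---
title: "Connectome-based prediction of anhedonia: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based prediction of anhedonia: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmnet)
```

# The analysis this package implements

`cpmnet` implements a four-stage functional-connectivity workflow for
studying anhedonia in major depressive disorder (MDD):

1. **Connectome-based predictive modeling (CPM)** of a behavioral score
   (by default the TEPS abstract consummatory pleasure subscale, where
   lower scores mean more severe anhedonia) from whole-brain
   functional-connectivity (FC) matrices, with leave-one-out
   cross-validation and a permutation test.
2. **Hub identification**: nodes with many incident edges in the
   cross-validated predictive network.
3. **Seed-based FC group comparison** between melancholic and
   non-melancholic patients at the hub seeds, with Bonferroni
   correction, followed by covariate-adjusted partial correlation of the
   top edge against clinical scores.
4. **RBF-SVM classification** of the two patient subtypes from the
   discriminating edge's FC value.

Because no clinical imaging data ship with the package, a seeded
synthetic cohort generator reproduces the statistical structure these
stages assume, and every stage is tested against it.

# The CPM model

Each subject $s$ carries a symmetric $N \times N$ FC matrix (here
$N = 246$ nodes), equivalently an edge vector
$x_s \in \mathbb{R}^{N(N-1)/2}$, plus a behavior score $y_s$. For each
leave-one-out fold, on the $n-1$ training subjects:

* **Edge selection.** Every edge is correlated with behavior (Pearson);
  the two-tailed p-value comes from
  $t = r\sqrt{(n_{tr}-2)/(1-r^2)}$ on $n_{tr}-2$ df. The positive
  network is $\{e : r_e > 0,\ p_e < p_{thr}\}$ (the negative network
  analogously).
* **Network strength.** A subject's strength is the sum of raw FC values
  over the selected edges, each unordered pair counted once.
* **Linear model.** Ordinary least squares of behavior on strength
  (intercept + slope), fitted on training subjects only; the held-out
  subject is predicted from its own strength under the training mask.

Performance is summarised by $r_{obs}$, the Pearson correlation of
observed and cross-validated predictions, and the mean squared
prediction error. Significance uses a permutation test: the behavior
vector is shuffled across subjects, the *entire* cross-validated
procedure re-run, and
$p = (1 + \#\{r_{null} \ge r_{obs}\})/(1 + N_{perm})$ (the add-one
estimator; ties count as exceedances, so $p \ge 1/(N_{perm}+1)$ and is
never zero).

## Tunable parameters

| parameter | default | why |
|---|---|---|
| `p_threshold` | $10^{-4}$ | the stringent whole-connectome selection level typical for CPM at ~30k candidate edges |
| `tail` | positive | the positive network is the headline model; `negative` and a combined positive-minus-negative predictor are available |
| `cv` | LOOCV | standard for CPM at modest samples; k-fold available |
| `n_permutations` | 5000 | conventional for a p floor of $\approx 2\times10^{-4}$; simulations in the tests use 200–1000 |
| `hub_threshold` | 5 edges | the degree at which a node is called a hub and promoted to seed status |
| SVM `c_grid`, `g_grid` | $2^{-5..15}$, $2^{-15..3}$, step 2 on the exponent | the LIBSVM practical-guide convention |
| SVM `k` | 5 folds | the workflow's stated cross-validation scheme |

## Numerical choices

* Leave-one-out training correlations are computed by *downdating*
  full-sample sufficient statistics (totals minus the held-out row),
  never by refitting per fold; a brute-force per-fold recomputation is
  kept as an oracle in the test suite and agrees to $10^{-10}$.
* The selection rule $p < p_{thr}$ is applied as $|r| > r_{crit}$ with
  $r_{crit}$ the exact inverse of the t transform at $p_{thr}$ — a
  monotone equivalence that avoids materialising a p-value matrix.
* Edges constant within a training fold have zero correlation variance;
  they get $r = 0$, $p = 1$ and are never selected.
* Folds whose mask is empty (common at stringent thresholds) predict
  the training-mean behavior and are flagged in the result; degenerate
  permutation iterations contribute $r_{null} = 0$ and are counted.
* FC matrices force their diagonal to exactly 1 after computation;
  generated edge values are clipped to $(-0.999, 0.999)$.
* SVM grid ties resolve to the smallest cost, then the smallest kernel
  width — the least complex model among equals.

# The synthetic cohort generator

The generator emulates a three-group study: 31 melancholic and 28
non-melancholic first-episode drug-naive MDD patients and 32 healthy
controls. Per group, behavioral scores (TEPS total and six subscales;
17-item HAMD) and covariates (age in years, education in years, illness
duration in months, framewise displacement) are truncated Gaussians with
the published group means and SDs, truncated at instrument bounds. Sex
is assigned by per-group male counts (10/10/15).

FC is generated at the edge level: each edge has a cohort-level
population mean drawn around 0.2 (SD 0.1, a typical resting-state FC
scale) and subject-level Gaussian noise with SD 0.15. Twenty-six
*planted* edges — 9 incident to an inferior-temporal-analog hub, 7 to a
parahippocampal-analog hub, 10 scattered — mix in the standardized
target score for patients so that each planted edge correlates with
behavior at `edge_behavior_r` (default 0.5); one hub-to-cingulate-analog
edge additionally carries a standardized melancholic-vs-non-melancholic
mean shift (`subtype_diff_d`, default −1.0, melancholic lower). An
optional time-series mode realises each matrix as 200 time points of
coloured noise (eigenvalue-clamped nearest positive-definite target)
whose empirical correlation approximates the target matrix.

Monte-Carlo checks in the test suite confirm the calibration: planted
edge-behavior correlations concentrate around their target, a zero
subtype effect leaves the patient groups matched on planted edges, and
with `edge_behavior_r = 0` the maximum edge-behavior correlation is
indistinguishable from pure noise.

## What the generator does *not* emulate

* **No spatial structure.** Edges are conditionally independent given
  the planted signal; real FC has strong spatial autocorrelation and
  network block structure.
* **Positive definiteness is not enforced.** All analyses consume edge
  values only, so matrices need not be valid correlation matrices of any
  latent signal (the time-series mode projects to the nearest PD matrix
  before colouring noise).
* **Behavioral subscales are drawn independently** (only per-scale
  means/SDs are published). Real TEPS subscales correlate strongly;
  consequently, cross-subscale associations (e.g. a planted edge against
  a non-target subscale) are null by construction here, and the partial
  correlation stage is exercised against the planted target score.
* No scanner physics, head motion, preprocessing artifacts or site
  effects.

Passing tests therefore demonstrate that the *procedures* are correct
and calibrated under the assumed statistical structure — not that the
pipeline would recover these effect sizes from real resting-state data.

# Design choices where the design was open

* **Pearson correlation on raw series** for FC; no Fisher z-transform is
  applied to stored FC, and network strength sums raw r values (not
  z-transformed, not averaged). Both are the most common reading of the
  workflow this package follows; the strength definition is configurable.
* **Consensus network = across-fold intersection.** A single predictive
  network is often visualised without stating the aggregation rule;
  intersection is the conservative choice and keeps the consensus a
  subset of every fold's mask (an invariant the tests assert).
* **Pooled-variance (Student) two-sample t** for the seed-FC comparison,
  matching the plain independent-samples t-test; Welch is a flag.
* **Bonferroni family size is always explicit** in outputs; by default it
  is the number of seed-target tests actually performed in the call,
  with duplicate unordered pairs tested once.
* **Partial-correlation p-values** use the t transform on the residual
  correlation with df reduced by the covariate count.
* **Non-nested SVM model selection**: the (c, g) grid is selected on the
  same five-fold split whose pooled metrics are reported, mirroring the
  common LIBSVM workflow. This inflates null accuracy by a selection
  bias of roughly +0.07 at n = 59 (measured in the test suite's
  label-shuffling calibration); nested cross-validation is the unbiased
  alternative and can be emulated by scoring a fresh fold split.
  Metric standard errors are SD of the per-fold metric / $\sqrt{k}$ —
  one of several possible definitions, recorded in the output metadata.
* **Permutation RNG**: one master seed generates all shuffles up front,
  so results are reproducible regardless of execution order.

# Simulation scale used by the tests

The package's own test suite runs its calibration suites at reduced
scale, chosen to give stable Monte-Carlo estimates: type-I calibration
of the permutation test with 100 replicate null cohorts (n = 30, 100
edges, 200 permutations); parameter recovery on 20 default cohorts at
`edge_behavior_r = 0.6`; seed-FC power on 50 cohorts (subtype shift
1.5 SD) and family-wise error on 200 null cohorts; classifier
calibration on 100 label shufflings. The acceptance script runs the
full 246-node pipeline with 1000 permutations.

# Known limitations

* LOOCV r can be biased slightly negative under the null (cross-validated
  predictions anti-correlate with held-out observations); the permutation
  test inherits and thereby accounts for this.
* The edge-level generator cannot probe robustness to realistic spatial
  correlation among edges, nor to motion or site confounds.
* The SVM stage reports no probability calibration or ROC analysis by
  design; it mirrors a confusion-matrix-centred workflow.
* Printed-summary ANOVA checks reproduce only rows whose statistics are
  consistent with a plain one-way ANOVA of the published means/SDs/ns;
  rows that are not internally consistent are excluded from checks.
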