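---
title: "Classifying lymph-node expression profiles with DLDA and nested cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lymph-node expression profiles with DLDA and nested cross-validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dldacv)
```

## The problem

A lymph-node biopsy suspected of lymphoma is classified today by histology
plus a battery of ancillary tests. Gene expression profiling offers a
single-platform alternative: hybridize patient RNA (Cy5) against a common
reference (Cy3) on a spotted two-colour microarray and let a classifier
assign the diagnosis — reactive lymphadenopathy (RL), classical Hodgkin
lymphoma (cHL), diffuse large B-cell lymphoma (DLBCL) or follicular
lymphoma (FL). This package implements that analysis as a tested pipeline:
spot-level preprocessing, gene ranking, diagonal linear discriminant
analysis (DLDA) under nested leave-one-out cross-validation (LOOCV),
three classification strategies with independent test-set evaluation, and
clustering/reporting — all driven by a synthetic-data generator with known
ground truth, so every stage can be verified without access to patient
arrays.

## Preprocessing model

**M/A values.** Each spot yields background-corrected channel intensities
`R` and `G` (median background subtracted, floored at 1 so logs stay
finite; the floor is the standard pragmatic choice when background exceeds
foreground). The analysis quantities are `M = log2(R/G)` and
`A = (log2 R + log2 G)/2`.

**Print-tip Lowess.** Intensity-dependent dye bias differs between the
pins that print the array, so a robust Lowess curve of `M` on `A` is
fitted *per print-tip group* (the `Block` of the spot file) and
subtracted. The span default of 0.3 (fraction of spots per local fit, 3
robustifying iterations) is the conventional choice for print-tip loess;
groups with fewer than 10 usable spots fall back to the whole-array fit.
Normalization is strictly within-array, so batches can never contaminate
each other; training (batch 1) and test (batch 2) matrices are assembled
separately.

**Array QC.** Arrays are scored by the median, over probes printed at
least twice, of the coefficient of variation of replicate background-
corrected intensities (averaged over the two channels); arrays scoring
above 1 are removed. The published analysis used a "QC CV score" with the
same threshold semantics from a quality-assessment package whose exact
formula is not recoverable; the replicate-CV median implemented here is a
documented, pluggable stand-in with the identical threshold-filter
contract. Arrays without replicated probes fall back to per-tip M
dispersion.

**Assembly.** Duplicate spots per probe are averaged; probes missing in
more than half the samples are dropped; remaining gaps take the probe's
median across samples. Probes are sorted (C collation), samples keep
sample-sheet order.

## Gene ranking and the classifier

**bss/wss.** For gene $g$ with class means $\bar{x}_{kg}$, grand mean
$\bar{x}_g$ and class sizes $n_k$:

$$\mathrm{BSS}_g = \sum_k n_k(\bar{x}_{kg}-\bar{x}_g)^2, \qquad
  \mathrm{WSS}_g = \sum_k \sum_{i \in k} (x_{ig}-\bar{x}_{kg})^2 .$$

Genes are ranked by $\mathrm{BSS}/(\mathrm{WSS}+\varepsilon)$ with
$\varepsilon = 10^{-12}$; zero-within-variance genes therefore rank first,
which matches the criterion's intent, and ties break by probe id so
rankings are reproducible. The $n_k$-weighted BSS is the standard ANOVA
decomposition; the source analysis does not state its weighting
convention, so this choice is documented rather than claimed.

**DLDA.** The classifier is Gaussian with a diagonal covariance shared
across classes: per selected gene it keeps class means and the pooled
within-class variance $s_g^2$ (denominator $n-K$, floored at $10^{-8}$).
A sample is assigned to the class minimizing
$\sum_g (x_g-\mu_{kg})^2 / s_g^2$. No priors enter by default — the pure
minimum-distance form standard for expression arrays, treating classes
evenly despite imbalance; a `priors` argument exists for users who want
the $-2\log\pi_k$ term. Ties go to the first class in sorted class order.

## Nested cross-validation

The error of a gene-set size $p$ is estimated by LOOCV with gene ranking
redone *inside every fold*: the held-out sample never influences which
genes are selected. Omitting this (ranking once on all samples) produces
the classic optimistic selection bias — the package's acceptance tests
demonstrate a gap of tens of accuracy points on pure-noise data.
`grid_search()` profiles $p$ over 10, 20, ..., 500 (50 sizes); the
optimal $p$ is the *smallest* size attaining the minimum error
(parsimony tie-break). Within each fold one ranking and one set of
per-gene statistics serve all grid sizes through cumulative score sums,
which is algebraically identical to refitting at every size — an
invariance the tests spot-check by recomputing grid points through the
single-size path. Training accuracy is `100 - min error`; the final rule
is refitted on the complete training set with the optimal number of
top-ranked genes (re-ranked on the full training data, not pooled from
fold-wise lists) and applied once to the independent test batch.

A property worth knowing when reading noise-floor numbers: on null data
at small $n$, LOOCV with centroid-type rules is *conservative* — removing
the held-out sample shifts its own class centroid away from it, and
in-fold selection amplifies the effect, so measured accuracy falls below
the 50% chance line (around 40–46% at 20 samples, approaching 50% only
for much larger cohorts), while the accuracy at the grid-selected optimum
drifts above it (winner's curse). The estimator never becomes optimistic,
which is what the selection-bias guard exists to establish.

## Classification strategies

Three families, mirrored in `default_strategies()`:

1. **Global multi-class** — one rule for RL v cHL v FL v DLBCL; samples
   of the heterogeneous "other NHL" pool are excluded as targets.
2. **Local binary** — two-group comparisons on subsets: all lymphoma v
   RL, cHL v NHL (RL excluded; the NHL side pools DLBCL, FL and other
   NHL), FL v DLBCL. Test evaluation uses only the relabelled subset of
   test samples, and this scope is deliberately documented because the
   source analysis leaves it ambiguous.
3. **Global binary (one-vs-rest)** — each diagnosis class against *all*
   remaining samples; "other NHL" cases strengthen the rest pool but are
   never a positive class.

## Reporting

Heat maps standardize each gene (z-score across samples), cluster genes
and samples by complete-linkage agglomeration on Euclidean distances of
those same standardized values, and use the red (high) to green (low)
scale with a class colour bar. Classifier-gene tables report the fold
change $2^{\bar{M}_\text{class}-\bar{M}_\text{rest}}$ — a class-vs-rest
contrast of mean log2 ratios. Whether published fold-change columns of
this kind are class-vs-rest or sample-vs-reference ratios is generally
unstated; the class-vs-rest reading is the natural one for
class-characteristic tables and is fixed here by definition, not claimed
as a reconstruction. Gene-list overlaps count shared probes between the
one-vs-rest classifiers and the multi-class signature.

## The synthetic-data generator

`sim_config()` defaults encode the two-batch study design: 116 samples in
five groups (RL 23, cHL 19, DLBCL 19, FL 35, other NHL 20) split 81/35
into a training and a test batch with the published per-class split, on
arrays of 2000 probes. Each class owns 20 informative genes (disjoint
sets) whose mean log2 ratio is shifted by `effect_size * noise_sd` in
that class. Defaults `effect_size = 2`, `noise_sd = 0.5` mean informative
genes are two-fold markers over a within-class SD of 0.5 log2 units —
strong but plausible marker behaviour; the source study reports neither
quantity, so these are testability choices, not biological claims. Gene
baselines are `N(0, 0.5)`; noise is homoscedastic Gaussian per gene
(matching the DLDA model assumptions), with a scaled-t option behind
`noise = "t"` for heavier tails. One master seed drives everything;
reruns are bit-identical.

The two-channel simulator lays each sample's expression onto a spotted
array: per-probe base intensities `A ~ N(10, 1.5)` with per-spot jitter,
a smooth per-print-tip dye-bias sinusoid of configurable amplitude added
to the true M (period 20 log2 units, i.e. a gentle drift across the
observed A range), channels reconstructed as `log2 R = A + M/2`,
`log2 G = A - M/2` over positive random backgrounds, 1% of spots flagged
bad, and each probe printed twice so replicate-CV QC is exercised. All
injected curves and per-spot truths are stored for recovery checks.

Normalization-recovery experiments use simulated *self-self* arrays
(reference RNA in both channels: no differential signal, spot noise SD
0.15) at the real platform's print density (19200 probes, 16 tips) — the
standard benchmark for assessing normalization, since it isolates the
smoother from biological spread. At patient-array noise levels the
max-abs curve-recovery statistic is dominated by smoother noise rather
than by bias removal.

What the generator does *not* emulate: spatial artefacts beyond print-tip
bias, probe cross-hybridization, batch-specific distributional shifts,
heteroscedastic gene variances, or correlated gene modules. Passing tests
therefore certify the algorithmic machinery, not clinical performance on
real biopsies; the published accuracy rates live on the deposited arrays
and are intentionally out of the package's reproduction scope.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
pp <- run_pipeline(cfg)
pp                       # per-strategy accuracy table
summary(pp$strategies$fl_v_rest)
plot(pp$strategies$multiclass$cv_profile)
```

Problem sizes throughout the test suite and the acceptance script (2000
probes for pipeline runs, 1000 for the noise and recovery studies, 50
noise replicates) are chosen so the full verification battery represents
each study condition at desk scale while remaining quick to run.

## Known limitations

* The QC score shares only threshold semantics with the original
  quality-assessment tool; scores are not numerically comparable.
* Accuracy under heavy class imbalance is reported as-is (no reweighting,
  matching the source protocol); per-class sensitivities accompany every
  strategy summary for transparency.
* LOOCV variance at these cohort sizes is substantial; grid-optimal
  accuracies carry a winner's-curse optimism that the independent test
  batch exists to expose.
* Between-array scale or quantile normalization, dye-swap designs and
  spatial (row/column) corrections are out of scope.
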