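---
title: "Conditional normalizing flows for rare-disease detection in PHR cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional normalizing flows for rare-disease detection in PHR cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

General-population personal-health-record (PHR) cohorts are dominated by
healthy participants: a condition such as diabetes may affect only 1--2% of
rows. Supervised classifiers degrade badly at such base rates — not because
the disease signal is absent, but because a handful of positive examples
cannot span the heterogeneity of how a disease manifests. `phrflow` takes the
semi-supervised anomaly-detection route instead: a density model is fitted to
*unaffected* participants only, and test rows are ranked by how improbable
they look under that model. Cases never enter training, so the approach is
indifferent to how few of them exist.

## The model

The density model is a conditional normalizing flow (CNF): an invertible map
$f_\theta(\cdot \mid c)$ from feature space to a latent space, conditioned on
a two-dimensional vector $c$ = (scaled age, gender). By the change of
variables,

$$\log p_X(x \mid c) \;=\; \log p_Z\!\big(f_\theta(x \mid c)\big) \;+\;
\log\left|\det \frac{\partial f_\theta(x \mid c)}{\partial x}\right|,$$

with $p_Z$ a diagonal-normal base distribution. Training minimizes the mean
negative log-likelihood of unaffected rows; at test time the anomaly score of
a row with latent image $z$ is $-\exp(-\lVert z\rVert^2/2)$, a strictly
increasing function of the distance from the latent origin.

The map is a composition of:

1. **A conditional affine transformation.** A linear–GeLU–linear network of
   the condition alone produces $(a, b) = \mathrm{SPLIT}(s(c))$; the layer
   computes $u = \exp(a')\odot x + b$ with $a' = \alpha\,\Psi(a)$. This is
   the only volume-changing layer; its log-determinant $\sum_i a'_i$ depends
   on the condition but not on $x$. $\Psi$ defaults to `tanh` and
   $\alpha$ to 1.9, a conventional soft clamp that bounds per-coordinate
   scales to $e^{\pm\alpha}$ and keeps optimization stable; both are
   configurable.
2. **Volume-preserving GIN coupling blocks.** Each block applies two
   coupling layers with swapped active/passive halves
   ($u_1 = x_1 \odot e^{\tilde s} + t(x_2, c)$, $u_2 = x_2$, subnetworks
   linear–ReLU–linear), then a fixed random permutation $R$ and a trainable
   global offset $t_{\text{global}}$. The raw scales $\tanh(s(x_2, c))$ are
   re-centered to sum to zero across the active coordinates before
   exponentiation, so every coupling layer has $|\det J| = 1$ exactly. This
   zero-sum re-centering is the standard general-incompressible-flow (GIN)
   construction; a plain affine coupling scale would not preserve volume, so
   the constraint is what reconciles expressive couplings with an exactly
   tractable, condition-only log-determinant.
3. **A diagonal-normal base** frozen at $\mathcal N(0, I)$ unless
   `learnable_base = TRUE`, in which case its mean and log-scales are trained
   — but only through the AltUB alternation (an extra base-only update every
   `altub_period` optimizer steps). AltUB is off by default: on some data the
   alternation destabilizes training, so it is opt-in.

The input dimension is always taken from the data at fit time and never
hard-coded; active/passive halves are $\lceil d/2\rceil$/$\lfloor d/2\rfloor$
for any $d$. The condition network outputs $2d$ values regardless of $d$.

All gradients are derived analytically (reverse-mode, layer by layer) and the
test suite verifies them against central finite differences to $10^{-6}$.
Optimization is Adam with a cosine-annealing-with-warm-restarts schedule
(linear warmup to `lr_max` over `warmup` epochs, half-cosine decay to
`lr_min`, restart every `cycle` epochs; defaults 3e-3/1e-5, warmup 5, cycle
50) and a global gradient-norm clip (default 2) — flow likelihoods
occasionally spike and the clip bounds the damage. Subnetwork output layers
initialize at zero, so the whole flow starts as a (permuted) identity with
zero log-determinant: a standard stable initialization for flows.

## Preprocessing, with a leakage guard

The chain is: `log(1+x)` on declared right-skewed features (step counts can
be zero, hence `log1p`), removal of filtered features — always including the
biomarker that defines the target label, which would otherwise leak the label
— chained-regression imputation, robust scaling $(x - \mathrm{median})/IQR$,
and PCA collapse of declared multicollinear groups (default one component per
group). Age and gender are routed to the condition matrix (age robustly
scaled with training parameters) and never appear among the features.

Choices worth stating:

* **Imputation** is chained ridge regression (penalty $10^{-3}$, at most 10
  rounds, convergence tolerance $10^{-3}$ on imputed cells, seed-controlled
  column order). The fitted per-round coefficients are stored and *replayed*
  at transform time, which makes `transform_cohort()` a pure function of the
  fitted state.
* **Zero-IQR columns** are centered and passed through with scale 1 rather
  than dropped: deterministic and information-preserving.
* **The leakage guard is structural**: `fit_preprocessor()` sees only the
  training rows, and the tests assert the fitted state is bit-identical when
  every test row is corrupted.
* Which features are "clinically irrelevant" is a domain judgment, so the
  drop list lives in the plan (configuration), not in code.

## Evaluation protocol

Unaffected rows are split 8:2 into a training pool and a shared test pool;
affected rows are partitioned into five near-equal subsets, and each test
fold is the pool plus one subset. Every fold's base rate therefore tracks the
cohort's (for 693 unaffected / 13 affected: 554 train, 139 pool, subsets of
3/3/3/2/2, fold base rates 0.014--0.021). Metrics are averaged over folds.
Supervised comparators need affected rows at training time, so they are
evaluated under a stratified 8:2 split whose single held-out fold conserves
the base rate the same way.

AUPRC is the primary metric and is computed as step-wise average precision
with tied scores grouped atomically — no linear PR interpolation, which is
known to flatter. A constant scorer then scores exactly the base rate, the
natural floor. AUROC uses the Mann–Whitney form with ties counted one half.
Repetition summaries report mean ± 1.96·sd/√n over seeded repetitions that
re-draw the split plan and model initialization (50 repetitions by default;
the bundled experiments use 10 to stay desk-scale). Welch's unequal-variance
t-test compares two models' retained per-repetition values; zero-variance
degenerate inputs resolve deterministically (p = 1 if equal means, p = 0
otherwise). In the positive-undersampling sweep each repetition also re-draws
*which* positives are excluded, so sweep means average over retained-case
subsets instead of inheriting the bias of a single draw.

Semi-supervised hyperparameter selection, when needed, uses a validation
fold assembled from the training pool plus one affected subset, which is then
excluded from final evaluation — the affected rows never touch model fitting
and the final test folds stay uncontaminated.

## The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, so
every stage is testable without access to any private cohort:

* demographics are matched exactly (no sampling of the margin); the default
  layout is a 706-participant adult cohort, 315 men / 391 women in five age
  bins, ages drawn uniformly within bins;
* features are Gaussian, lognormal (right-skewed, strictly positive — AST,
  ALT, triglyceride, daily step count), or ordinal (latent-Gaussian grades,
  e.g. polygenic-risk categories); equicorrelated blocks come from a
  single-factor construction, which is the simplest structure that makes PCA
  collapse meaningful; age/gender shift feature means linearly;
* disease labels are deterministic thresholds on a biomarker, with
  `calibrate_base_rate()` setting the cut at the appropriate quantile of a
  large simulated cohort; the bundled six "diseases" target prevalences
  0.33, 0.02, 0.08, 0.08, 0.11, 0.34, spanning the imbalance spectrum;
* missingness is injected completely at random per feature *after* label
  computation, at 2--10% per feature. Real PHR missingness mechanisms are
  unknown to us, so MCAR is an explicit, arbitrary default — passing tests
  say nothing about informative missingness.

### Why cases are explicitly mean-shifted

A first design made cases *only* the upper tail of the defining biomarker,
which is part of an equicorrelated glycemic block. That turns out to be
nearly undetectable by any whitening density model, for a clean geometric
reason: selecting the tail of one scalar shifts the affected mean along a
single direction (the block factor), and the whitened noncentrality of such a
shift is bounded by $(\mathbb E[z \mid z > q_{0.98}])^2 \approx 5.9$ no
matter how large or tightly correlated the block is. Empirically a
Mahalanobis oracle topped out near AUROC 0.66 on the full feature set. Real
disease is not a tail artifact: a manifest case sits far outside the healthy
distribution in several markers (a diagnosed diabetic is ~3 sd above the
population HbA1c mean). The benchmark cohort therefore applies an explicit
manifestation model to affected rows: three subtypes with distinct
signatures — insulin-deficient (high HbA1c/fructosamine, *low* C-peptide,
breaking the block correlation), insulin-resistant (high HOMA-IR/C-peptide
with BMI and triglyceride), lifestyle-metabolic (BMI, steps, triglyceride,
blood pressure) — and a per-case severity factor uniform on [0.4, 1.6]
(mean 1). Labels remain deterministic thresholds on the unshifted defining
biomarker.

The heterogeneity is what gives the benchmark its point: a supervised
learner with a handful of positives cannot cover three signatures (and the
two C-peptide directions actively conflict in a single split), while a
density model trained only on normals flags any deviation direction. That is
precisely the mechanism by which semi-supervised detection is expected to
overtake supervised classification as positives become scarce.

### What the generator does not emulate

Real feature counts (hundreds of survey/genetic/wearable variables),
informative missingness, measurement error structure, nonlinear age effects,
label noise, and any real biomarker catalogue. Green tests demonstrate that
the pipeline recovers structure it is designed to see at desk scale — they
are not clinical validation.

## Problem sizes and defaults used by the bundled experiments

The bundled benchmark runs a 3 000-participant cohort at base rate 0.02 with
10 repetitions; the undersampling sweep uses 1 500 participants at base rate
0.10 over fractions {0, 0.2, 0.5, 0.8, 0.95} with 10 repetitions. The
default experiment flow is 3 coupling blocks of hidden width 32 trained for
120 epochs at batch size 128 — small enough that a full repetition fits in
seconds on one CPU core, large enough to whiten the benchmark's
block-correlated, condition-shifted features (held-out unaffected rows reach
mean $\lVert z\rVert^2/d$ within [0.7, 1.3]). The flow-level default of 8
blocks and width 64 (`flow_config()`) remains the recommendation for real
data of ~50 features.

## Baselines and resampling

Supervised comparators (histogram gradient-boosted trees — the `"lgbm"`
scorer, backed by xgboost's `tree_method = "hist"` — random forest, RBF-SVM)
use inverse-frequency class weights by default and can tune small grids by
5-fold CV maximizing AUPRC. One observation from this package's synthetic
family is worth recording: class weighting reliably *changed* the fitted
boosted-tree models but did not improve their AUPRC (across paired seeds it
was neutral-to-slightly-negative), consistent with ranking metrics being
largely insensitive to loss reweighting; the tests therefore assert the
weighting contract, not a benefit. The classical one-class detectors are an
RBF one-class SVM, an isolation forest (implemented in-package: random
subsampled trees, uniform splits, path-length score), and a Gaussian mixture
density (EM via mclust, component count by BIC from {1, 2, 4, 8}, scored by
negative log-density). All scorers share one interface — `fit(x, cond, y,
seed)` / `score(model, x, cond)`, higher = more anomalous/positive — and the
supervised ones consume age and gender as ordinary features, since only the
CNF has a conditioning channel. SMOTE, ADASYN and Tomek-link resampling are
implemented with their defining post-conditions asserted in tests
(oversamplers only interpolate between minority neighbours; Tomek only
removes majority members of mutual opposite-class nearest-neighbour pairs).

## Numerical choices and degenerate inputs

* Forward/inverse round-trips hold to $10^{-5}$ across the full stack; the
  analytic log-determinant matches numerical Jacobians to $10^{-3}$ at
  $d \le 8$; GIN layers are volume-preserving to $10^{-6}$; the modeled
  density integrates to 1 within 2% at $d = 2$.
* A coupling layer whose active half has a single coordinate is forced to
  scale 1 by the zero-sum constraint; harmless, but a reason to keep
  $d \ge 4$ in practice.
* Anomaly scores underflow to exactly 0 when $\lVert z\rVert^2 \gtrsim
  1490$; such rows tie with each other but still rank above all normal
  rows, and ties are handled atomically in both metrics.
* Empty cohorts, all-missing labels, constant features, single-class folds
  and affected-contaminated training sets all either produce defined output
  or fail fast with a protocol error; see the test suite.

## Known limitations

The flow is a dense, small-data model: no minibatch parallelism, no GPU, and
the analytic backprop covers exactly the published architecture (swapping in
other couplings would require new derivative code). The generator's MCAR
missingness and linear condition effects are simplifications. AUPRC at very
low base rates is estimated from one or two positives per fold and is
accordingly noisy even after averaging; the repetition machinery quantifies
but cannot remove that noise.
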