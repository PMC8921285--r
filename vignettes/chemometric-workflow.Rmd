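---
title: "A validated PLS-DA workflow for urinary metabolomics biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A validated PLS-DA workflow for urinary metabolomics biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

# The problem

Untargeted LC-MS metabolomics of urine produces peak tables with a few dozen
samples and thousands of aligned features. Discriminating two clinically
similar groups — here prostate carcinoma (PCa) against benign prostatic
hyperplasia (BPH), 20 samples each — from such a table invites overfitting:
any flexible classifier can separate 40 points in a 2000-dimensional space.
This package implements a defensible workflow for that regime:

1. **QC-anchored preprocessing** that removes contaminated and unstable
   features and corrects instrumental drift before any modeling;
2. **PLS-DA** (partial least squares regression on a coded class variable)
   as the classifier, appropriate when variables vastly outnumber samples;
3. **repeated double cross-validation (r-dCV)** so every figure of merit is
   estimated on samples external to both model fitting and model selection,
   with nonparametric confidence intervals from the repetition distribution;
4. **permutation testing** to verify that the same machinery applied to
   label-randomized data performs at chance;
5. **rank-product + VIP variable selection** aggregated over the r-dCV
   sub-models, reducing thousands of features to a small biomarker panel
   that is then re-modeled from scratch;
6. **ROC/AUROC estimation** averaged over the cross-validation repetitions,
   and per-metabolite univariate baselines.

Because no patient-level data are distributed with studies of this kind, the
package ships a synthetic-data generator that reproduces the acquisition's
statistical structure with known ground truth, so every stage can be tested
for parameter recovery.

# The synthetic acquisition

`simulate_feature_table()` emulates one injection sequence: blank
injections, ten conditioning QC injections that equilibrate the
chromatographic system, then the randomized study samples in blocks of five,
each block followed by one pooled-QC injection.

The generative model, feature by feature:

* **Baseline.** Log peak areas are Gaussian: feature baselines spread
  (SD 1) around `base_log_mean` (default `log(1e6)`), and biological
  between-sample variation has SD `base_log_sd` (default 0.5, i.e. roughly a
  50% biological CV — typical for urinary metabolites). Areas are therefore
  log-normal: positive and right-skewed, as peak areas are.
* **Dilution.** Urine concentration varies between voids. Each sample's
  creatinine is log-normal (default median 100 mg/dL, log-SD 0.4), and all
  of that sample's areas scale proportionally with its concentration. This
  coupling is what makes creatinine normalization meaningful: dividing by
  creatinine removes the dilution spread up to a constant that autoscaling
  absorbs. The optional 5 mg/dL outlier exercises the normalization path on
  an anomalously dilute urine.
* **Class effects.** `n_discriminant` features (default 22) receive a
  log-scale mean shift of `effect_size * base_log_sd` between classes, with
  a configurable fraction overexpressed in PCa. `effect_size` is therefore
  the class separation in within-class SD units; the default 1.5 gives a
  clearly detectable but individually imperfect marker (two-sample t-test
  power ≈ 0.95 at n = 20 + 20), which is the interesting regime for
  multivariate selection.
* **QC rows.** The pooled QC is the per-feature mean of the sample areas
  (pooled-aliquot semantics) times multiplicative log-normal technical noise
  with relative SD `qc_rsd` (default 0.10; the acquisition literature treats
  QC RSD below 20–30% as acceptable, so 0.10 models a well-behaved batch).
* **Artifacts with ground truth.** A planted subset of features appears in
  blanks at 20% of the QC mean (safely above the 10% carry-over rule);
  another subset alternates ±50% across QCs (guaranteeing QC RSD above the
  25% filter even in otherwise noise-free settings); another is zeroed in
  one monitoring QC. A configurable fraction of features drifts linearly
  with injection order (default 30% at 0.5%/injection). The returned
  `sim_truth` records every planted index, so tests can assert that the
  filters remove *exactly* the planted artifacts and that selection recovers
  the planted biomarkers.

What the generator does **not** emulate: retention-time misalignment,
missing-value structure in samples, correlated metabolite families,
nonlinear or batch-step drift, and heavy-tailed single-sample artifacts.
Passing tests on synthetic data therefore demonstrate the machinery's
correctness and its statistical calibration under the stated model — not
performance on any particular real cohort.

# Preprocessing decisions

The chain runs in a fixed order: blank/carry-over filter → QC drift
correction → QC presence/RSD filter → creatinine normalization. Autoscaling
is deliberately *not* part of the chain: it is refit inside every
cross-validation split (see below).

* **Carry-over reference.** A feature is discarded when its mean blank area
  exceeds 10% of its mean QC area. The QC mean is the natural denominator
  because the pooled QC represents the average sample.
* **Drift correction.** Per feature, an OLS line of QC area on injection
  order is fitted over the *monitoring* QCs only — QCs injected before the
  first sample condition the system and are excluded. All rows are then
  detrended additively, anchored at the mean QC injection order, flooring
  negative results at zero; zero areas denote non-detected peaks and stay
  zero. The correction is idempotent, and a multiplicative variant is
  available (`method = "multiplicative"`) for drift proportional to
  intensity. Additive is the default because it is exact for the linear
  trend model and cannot blow up low-intensity features with small QC
  intercepts.
* **RSD convention.** The stability filter uses the sample (n−1) standard
  deviation over QC areas, conventional for the small QC counts of a single
  batch (9 monitoring QCs at the default layout).
* **Presence rule.** Only QC presence is a filter criterion; features
  absent from some *study samples* are retained, since genuine biomarkers
  may be absent from one class.
* **Creatinine normalization** divides each sample row by its creatinine
  concentration (plain division; any reference-concentration convention
  differs only by a global constant that autoscaling absorbs). QC rows are
  pooled material without a creatinine value and pass through unchanged.

# The classifier and the validation engine

`plsda()` codes the classes −1 (BPH) / +1 (PCa) and fits PLS1 by NIPALS
with X-only deflation. The continuous prediction — the *canonical score* —
is thresholded at zero; an exact zero goes to the negative class so the rule
is deterministic. At full rank the PLS solution coincides with OLS, which
the tests exploit as an oracle.

`rdcv_plsda()` wraps the classifier in two nested cross-validation loops:
10 outer deletion groups whose held-out samples mimic an external test set,
and 8 inner groups on each calibration set that select the latent-variable
count (smallest count minimizing inner misclassification; ties go to the
more parsimonious model, so pure-noise data collapse to one latent
variable). The whole procedure repeats 30 times with reshuffled splits,
yielding distributions of every figure of merit, sample score and
coefficient; intervals are nearest-rank percentiles (no interpolation
ambiguity). Splits are stratified by class by default — with 20 + 20
samples every outer group holds exactly 2 + 2 — which keeps calibration
sets balanced and the null behavior centered.

Two contracts are enforced structurally and covered by tests:

* **No leakage.** Autoscaling parameters, block norms, latent-variable
  counts and coefficients are computed from calibration rows only. The
  inner split of each outer fold draws from a pre-assigned seed, so even
  RNG consumption cannot couple validation data to the fitted models:
  corrupting a validation fold leaves its predicting model bit-identical.
* **Determinism.** Given `seed`, the full result reproduces exactly.

`max_lv` defaults to 5: with 36-sample calibration sets, models beyond five
latent variables are rarely selected and mostly encode noise; the ceiling
is a search bound, not a modeling assumption, and is configurable.

# Variable selection

Within each run, the calibration sub-models of one inner cross-validation
are harvested: their coefficient vectors and VIP vectors at the selected
latent-variable count. At the defaults this gives 30 × 8 = 240 sub-models.
(An alternative `harvest = "nested"` collects every outer fold's inner
models.) Selection then proceeds:

1. within each sub-model, rank variables by |coefficient|, rank 1 the most
   contributing, average ranks on ties;
2. aggregate each variable by its **rank product** — the geometric mean of
   its ranks, computed as `exp(mean(log(rank)))`;
3. select variables with rank product strictly below the geometric mean of
   all rank products;
4. retain only those whose mean VIP over the sub-models exceeds 1 (the
   conventional relevance rule).

The reduced panel is then re-modeled by a fresh `rdcv_plsda()` call, and in
a two-block design the reduced blocks are fused by scaling each autoscaled
block to unit Frobenius norm (norms learned on calibration rows inside CV)
before concatenation, so neither ionization mode dominates by column count.

The geometric-mean threshold is adaptive rather than a fixed quantile: on
null data it selects an unremarkable, seed-unstable subset (tested), while
planted signal pulls the threshold down and concentrates the selection on
the true discriminants — at the default study conditions the planted panel
is recovered essentially completely.

# Permutation test

The null distribution of the figures of merit comes from refitting the
classifier under random label permutations. By default each permutation is
evaluated with a single double-CV pass whose latent-variable count is fixed
at the unpermuted model's modal count — the *reduced scheme*, which makes
1000 randomizations feasible in minutes; `scheme = "full"` reruns the whole
r-dCV per permutation. P-values use the standard add-one estimator
`(1 + #{null ≥ observed}) / (B + 1)` (direction reversed for the error
rate), so they are bounded below by `1/(B+1)` and never zero. On synthetic
data with planted signal the null accuracy centers at 50%, reproducing the
expectation that no random labeling simulates a correct classification.

# ROC summaries

Per run, a threshold sweep over the outer-loop scores yields one ROC curve;
the AUROC (trapezoid rule) equals the normalized Mann–Whitney U statistic,
which the tests verify by brute-force pair counting. Curves are averaged
vertically on a fixed 101-point false-positive-rate grid — a common-grid
convention chosen for determinism — and the AUROC is reported as mean plus
nearest-rank percentile interval across runs. `univariate_performance()`
runs the identical engine on a single metabolite (one latent variable), so
multivariate and single-marker performance are compared like for like;
`two_sample_t()` supplies the accompanying pooled-variance Student's
t-tests (Welch by flag), from raw vectors or summary statistics.

# Numerical choices and degenerate inputs

* NIPALS stops early when the residual covariance underflows; requesting
  more components than the matrix rank is an error in `plsda()` and a
  truncated-with-warning candidate list inside the inner search.
* Zero-variance columns make autoscaling impossible and raise an error
  naming the columns.
* A feature with QC mean 0 is dropped by the presence rule, never a
  division error; RSD of a zero-mean feature is treated as infinite.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive; Hotelling's T² uses the n−1 variance
  convention, so its per-sample mean is exactly `A(n−1)/n`.
* All percentile intervals use the nearest-rank rule.

# Problem sizes used in the test suite

The simulated studies in the tests use 20 + 20 samples with 200 features
(22 planted), the acceptance-style checks use 30 r-dCV runs, 200 label
permutations and 20 replicate studies for selection recovery — sizes chosen
so the full statistical behavior (null centering, separable limits,
recovery rates) is exercised while the suite stays comfortably
interactive. The generator and engine scale to the thousands of features of
a real acquisition with the same code paths.

# Known limitations

* Two classes only; no multi-class or orthogonalized PLS variants.
* No batch-to-batch correction: one injection sequence is assumed.
* The permutation test's reduced scheme fixes the latent-variable count,
  slightly narrowing the null's variance relative to a full re-selection
  per permutation; the full scheme is available when runtime permits.
* No external test-set evaluation: r-dCV is the validation strategy, and
  its figures of merit are internal-validation estimates.
* The t-tests are reported without multiple-testing correction, as
  univariate descriptors next to the multivariate model rather than as an
  inferential screen.
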