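---
title: "Methods: differential-sensing analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential-sensing analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelsense)
```

## The measurement model

A differential sensor array consists of many low-specificity receptors —
here, self-assembling peptide barrels with solvent-accessible channels —
each loaded with an environment-sensitive dye that fluoresces only when
bound. An analyte competes with the dye for the channel; how much dye it
displaces from each receptor depends on the receptor's size, shape and
chemistry. The vector of fluorescence losses across the array is the
sample's *fingerprint*, and classification of fingerprints, not any single
receptor's response, identifies the analyte.

`barrelsense` covers the full statistical path: reference-based
normalization, replicate aggregation, outlier screening, cross-validated
classification, receptor-importance ranking, and reduced-panel
comparisons. Because wet-lab plate data are not generally available for
method development, the package carries a first-class simulator whose
outputs have the same schema as real plate exports and whose ground truth
(class labels, informative receptors, distorted wells) is known exactly.

## Normalization

A raw sample well `X` is scaled as `(X − Min_AF)/(Max − Min_F)`, with
`Max` the receptor + dye wells, `Min_F` the dye-alone wells and `Min_AF`
the analyte + dye wells on the same plate. Two properties are worth making
explicit, and are asserted as exact identities in the test suite:

* **Gain invariance.** All four signals scale with the same optical gain,
  so any multiplicative plate or instrument factor cancels exactly.
* **No clipping.** Values below 0 (autofluorescence exceeding the residual
  signal of a strongly displaced dye) and above 1 (noise around an
  undisplaced receptor) are genuine and retained; clipping is a
  visualization choice, not a processing step.

Reference scope is per plate by default — references are dispensed on
every plate, and per-plate scoping is what makes the gain cancellation
exact — with a pooled `"global"` scope available for designs without
per-plate references. Multiple reference wells of the same role are
combined by median before the ratio is formed. Technical replicates of a
sample are likewise collapsed by the per-receptor median, which absorbs a
single gross replicate error without any explicit rule.

A receptor whose reference range `Max − Min_F` is non-positive, or below
5% of the plate's median range, has no usable dynamic range. This is how
the two control channels (a receptor-free blank and a non-binding bundle)
identify themselves, and also how a receptor with too little loaded
fluorescence is caught. Such receptors are excluded panel-wide and
reported, because a receptor usable on some plates only would leave most
fingerprints incomplete.

## Outlier screening

Readings are screened with the generalized ESD (Rosner) procedure. For up
to `k` candidate outliers (default `floor(n/3)`, capped at `n − 2`), the
most extreme remaining point is set aside at each iteration and

\[
R_i = \max \frac{|x - \bar x|}{s}, \qquad
\lambda_i = \frac{(n-i)\,t_{p,\,n-i-1}}{\sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}},
\quad p = 1 - \frac{\alpha}{2(n-i+1)} .
\]

The outlier count is the *largest* `i` with `R_i > λ_i` — a later
exceedance rescues earlier non-exceeding iterations, which is exactly what
distinguishes this procedure from repeated Grubbs testing and lets it
handle masking pairs. Ties on the extreme point break to the lowest index
for reproducibility; an all-equal sample flags nothing.

The population each reading is tested against is, by default, the
same-class fingerprints' values for one receptor: replicate samples of one
analyte are the natural null population. A `"global"` per-receptor
grouping is available for unlabelled data. Groups smaller than 4 are
skipped with a warning. A fingerprint with at least `drop_threshold`
flagged readings (default 2) at `alpha = 0.05` is excluded whole.

The implementation is verified against an independently coded brute-force
oracle (sequential extreme removal with freshly computed t-quantiles) on
1,000 randomized vectors, and its α-calibration is tested both ways: gross
planted outliers are always caught at α = 0.05, and the flag rate vanishes
as α → 0. At the group sizes typical for this design (n ≈ 10) the
approximate critical values are known to be slightly permissive (we
measure ≈7–8% of pure-Gaussian groups yielding at least one flag at
α = 0.05); the drop-threshold rule is what keeps this from discarding
fingerprints wholesale, since two same-fingerprint false flags must
coincide.

## Classification

Nested stratified cross-validation (defaults: 5 outer folds, 3 inner) is
the performance estimator. Stratification deals samples of each class
round-robin into folds after shuffling, so per-fold class counts deviate
from proportionality by at most one; if a class has fewer members than
folds, the fold count is reduced with a warning rather than silently
losing a class from a fold. Inside each outer training set an inner CV
selects hyperparameters by accuracy (ties to the first grid point); the
outer test fold is used exactly once. The test suite asserts the
no-leakage property directly: corrupting an outer test fold's feature
values does not change that fold's hyperparameter selection.

The algorithm roster is the standard spot-check set — Gaussian naive
Bayes, k-nearest neighbours, linear discriminant analysis, AdaBoost, and
support vector classifiers with linear and RBF kernels — plus two dummy
baselines that assign labels at random (uniform, or from training class
priors) and bypass the inner loop. Grids are deliberately small
(neighbours {1, 3, 5}, SVC cost {0.1, 1, 10}, boosting rounds {25, 50}):
the point is to spot-check algorithms, not to tune them heavily, and small
grids keep the inner loop honest at these sample sizes. Classifier
internals are delegated to established implementations (e1071, MASS,
class, rpart-based SAMME boosting, ranger); the harness — stratification,
metrics, leakage control — is owned by this package. Features enter on the
normalized scale without re-standardization by default, since the
normalization already fixes the scale; per-feature z-scoring (computed on
training folds only) is available as a flag.

Metrics are accuracy, macro-averaged precision and macro-averaged F1 in
percent, reported as mean ± sd over outer folds with the pooled confusion
matrix; pooled-confusion accuracy equals the sample-weighted fold mean by
construction, and the suite asserts it. Group-level (e.g. brand-level)
predictions are majority votes over a group's samples, with ties broken by
global predicted-class frequency and then lexicographically, and the tie
recorded.

## Receptor importance and panel reduction

Three importance views are computed per receptor: the one-way ANOVA F
statistic across classes (KBest; a zero within-class variance with
non-zero between-class variance is a perfect separator and scores
infinite, ranked first), impurity importance from extremely randomized
trees, and permutation importance (mean held-out accuracy drop over 50
shuffles of one feature's column, on a stratified 2/3–1/3 split; negative
values are possible and meaningful). Each method yields ranks (ties
averaged), and the per-method ranks are summed into the combined ranking;
ordering ties break by ANOVA-F rank, then identifier. The combined rank is
inherently invariant to method order.

Reduced panels (top-k receptors) are retrained from scratch and compared
with the full array using the combined 5×2 CV F-test: five independent
stratified 2-fold splits, fold error differences `p_i^{(j)}`,
per-repetition variances `s_i^2`, and
`f = Σ p_ij² / (2 Σ s_i²)` referred to F(10, 5). Squaring makes the test
two-sided; swapping the classifiers negates the differences and leaves `f`
unchanged (asserted). If every repetition has zero variance — identical
predictions everywhere, e.g. a panel compared against itself — the
statistic is undefined and the result is flagged degenerate with p = 1:
identical behaviour is no evidence of a difference. The 2-fold splits are
stratified because halving small per-class counts without stratification
regularly produces single-class training halves. Type-I calibration is
checked by simulation: two reasonable classifiers on pure-noise features
reject at ≈5% (the acceptance suite requires the rate to lie in
[0.01, 0.10] over 200 null datasets).

## What the simulator emulates — and what it does not

The generator's defaults are the study conditions used throughout the
tests: 5 analyte classes, 10 independently prepared samples per class, 4
technical replicates per sample, a 46-receptor panel plus 2 controls,
screening at α = 0.05 with drop threshold 2.

Binding follows single-site competitive equilibrium,
`θ = (D/K_D)/(1 + D/K_D + Σ (c_a/K_a)^h)` with the Hill exponent `h`
defaulting to 1 (no cooperativity; the parameter exists for sensitivity
analyses). This is the minimal model consistent with a dye-displacement
readout. Well intensity is
`gain × (baseline × θ + dye background + autofluorescence) + noise`, so
with all noise terms zero the full pipeline reproduces the analytic ratio
`θ_with/θ_without` to floating precision — the round-trip is a test.

Informative receptors are planted by giving them class-dependent
affinities spanning a chosen fold change (multipliers log-spaced, assigned
to classes in a random order per receptor so that no single receptor
suffices by construction); the stored ground-truth flag is re-derived from
the affinity matrix by the 2-fold ratio rule rather than copied from the
planting. Affinities themselves are free parameters drawn from log-normal
distributions — they are not estimates of any real receptor panel, and
nothing in the package should be read as a binding-constant prediction.

Noise structure and chosen defaults, with units:

* `replicate_noise_sd = 0.05` (normalized-signal units): Gaussian well
  noise, converted per well to intensity units via the receptor's
  reference range.
* `plate_gain_sd = 0.05` (log scale): multiplicative log-normal per-plate
  gain. It cancels exactly in normalization with per-plate references;
  it is present so that the `"global"` reference scope degrades
  realistically.
* `autofluorescence = 30 a.u.`, `dye_background = 50 a.u.` against loaded
  intensities of ~1000 a.u.
* `outlier_rate = 0.01` per well, `outlier_magnitude = 5`: a failed well's
  intensity is multiplied by 5 or 1/5 with equal probability — gross,
  liquid-handling-style distortions on the raw scale, so the ESD screen is
  exercised on realistic artifacts rather than on pre-normalized
  convenience values.

The plate layout dispenses three replicate loaded-receptor reference
blocks, four dye-alone wells and four autofluorescence wells per class on
every 384-well plate, with four sample blocks filling the remainder.
Median-of-three references are robust to a single gross failure; an
earlier single-well reference design let one failed autofluorescence well
corrupt a whole fingerprint across all receptors, which inflated exclusion
far beyond what the assay this emulates reports. Under the defaults the
screen retains roughly 40–45 of 50 fingerprints, in line with the
reductions typical of real campaigns.

What the simulator deliberately does not model: binding kinetics and
fluorescence photophysics (equilibrium intensities only), spectral
cross-talk, spatial plate gradients (edge effects), correlated receptor
chemistries (affinities are drawn independently per receptor), and any
sequence-to-affinity relationship. Tests passing on synthetic data
therefore demonstrate the *statistical machinery* — normalization algebra,
screening calibration, leakage-free estimation, recovery of planted
signal — not the chemistry of any particular array.

## Numerical choices and degenerate inputs

* Zero reference range raises an error in the scalar normalizer and a
  reported panel-wide exclusion in the table path.
* ESD with zero variance at the first iteration returns an empty flag set;
  later zero variance truncates the iteration.
* `which.max` tie-breaking (lowest index) fixes ESD and vote ties;
  PCA component signs follow the largest-magnitude-loading-positive
  convention so projections are order-invariant and reproducible.
* Constant receptors yield `NA` Spearman correlations (warned, not
  fabricated) and zero ANOVA-F scores.
* All stochastic functions take a `seed` argument and restore the
  caller's RNG state; identical configurations give byte-identical
  simulated datasets and identical reports.

## Problem sizes used in the checks

The bundled verification runs use the study conditions above (50
fingerprints by 46 receptors per dataset), 1,000 randomized vectors of
n ≤ 15 for the ESD/oracle equivalence, 200 planted-outlier and 200
vanishing-α vectors, 200 null datasets (n = 60, 8 features) for the F-test
calibration, and 10–20 repeated simulations for dummy calibration,
feature recovery, and the separable-panel checks. These sizes give stable
Monte-Carlo estimates at the stated tolerances while keeping a full run in
the low minutes on a single CPU.

## Known limitations

* The ESD grouping choice (per class vs global) changes flag counts on
  real data with strong class structure; the default is principled, but
  both are exposed because assay reports rarely state the grouping.
* The inner-loop objective is accuracy; with strongly unbalanced classes a
  macro-F1 objective could select differently (class balancing is
  deliberately out of scope).
* Permutation importance uses a single stratified split for speed;
  repeated-split averaging would reduce its variance at proportional cost.
* AdaBoost is SAMME over depth-1 stumps; it is the weakest of the six on
  smooth multiclass boundaries, which is expected and mirrors its role as
  a spot-check rather than a tuned contender.
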