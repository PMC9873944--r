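# barrelsense

Differential sensing with arrays of low-specificity receptors — for example
de novo designed α-helical barrels loaded with an environment-sensitive
reporter dye — identifies analytes not by a single specific binding event
but by the *pattern* of responses across the whole array. Each analyte
displaces the dye differentially across the receptors, the loss of
fluorescence is read on 384-well plates, and the resulting per-sample
"fingerprint" is classified by machine learning. `barrelsense` implements
the complete analysis for such dye-displacement arrays, from raw
plate-reader tables to cross-validated classifiers and reduced sensor
panels, together with a competitive-binding simulator so the whole pipeline
can be exercised, tested, and calibrated on synthetic data with known
ground truth.

The package is aimed at chemists and data scientists running
indicator-displacement / differential-sensing campaigns ("electronic
tongue" style assays) who need a reproducible, leakage-free statistical
pipeline rather than ad hoc spreadsheets.

## The analysis

**Normalization.** Every sample well `X` (receptor + dye + analyte) is
min–max scaled against its plate's reference wells:

```
normalized = (X − Min_AF) / (Max − Min_F)
```

where `Min_AF` is the analyte + dye well (correcting analyte
autofluorescence), `Max` the receptor + dye well, and `Min_F` the dye-alone
well. The scale anchors at 1 for an untouched loaded receptor and 0 for
fully displaced dye; values are never clipped, so strong displacement plus
autofluorescence can legitimately go negative. Technical replicates are
collapsed by the per-receptor median.

**Outlier screening.** Readings are screened with the generalized extreme
Studentized deviate (ESD) test of Rosner (1983): iteratively remove the
point maximizing `|x − mean|/sd` and compare `R_i` against the
t-distribution critical value `λ_i`; the number of outliers is the largest
`i` with `R_i > λ_i`. A fingerprint accumulating at least `drop_threshold`
flagged readings (default 2, at α = 0.05) is excluded entirely.

**Classification.** Six spot-check algorithms (Gaussian naive Bayes,
k-nearest neighbours, linear discriminant analysis, AdaBoost, linear and
RBF support vector classifiers) plus two random-label dummy baselines run
under nested stratified cross-validation: an inner CV on the training folds
picks hyperparameters, the outer fold is touched exactly once. Metrics are
accuracy, macro precision and macro F1, reported as mean ± sd across outer
folds.

**Panel reduction.** Receptors are ranked by three importance methods —
per-feature one-way ANOVA F (KBest), extremely-randomized-trees impurity
importance, and permutation importance — and the three ranks are summed
into one combined ranking. A reduced array of the top-k receptors is
retrained and compared against the full array (and against the dummies)
with the combined 5×2 CV F-test of Alpaydin (1999):
`f = Σ p_ij² / (2 Σ s_i²) ~ F(10, 5)` under the null of equal performance.

**Simulator.** Receptor–dye–analyte competition follows single-site
equilibrium: occupancy `θ = (D/K_D) / (1 + D/K_D + Σ c_a/K_a)`. The
generator lays out 384-well plates with replicated reference wells,
per-plate gain, replicate noise, analyte autofluorescence, and sporadic
gross liquid-handling failures, and records which receptors are truly
informative (class-dependent affinities) so recovery can be verified.

## Worked example

```r
library(barrelsense)

panel <- sim_panel(n_barrels = 46, n_classes = 5, n_informative = 10, seed = 11)
sim   <- simulate_raw_plates(panel, sim_config(seed = 12))

fps <- preprocess_plates(sim$readings)     # 50 median fingerprints x 46 barrels
scr <- screen_fingerprints(fps)
scr
#> <bs_screen> 50 fingerprints in, 40 retained, 10 dropped (alpha = 0.05, drop threshold = 2)
#> 33 flagged reading(s) across 22 fingerprint(s)

cv <- nested_cv(scr$retained, classifier_spec("gaussian_naive_bayes"), seed = 13)
cv
#> <bs_cv> gaussian_naive_bayes, 5-fold outer / 3-fold inner nested CV on 40 samples, 46 features
#>   accuracy 100.0 +/- 0.0 %

rk <- rank_barrels(scr$retained, seed = 14)
head(tibble::as_tibble(rk)[c("feature", "kbest_rank", "tree_rank", "perm_rank", "combined_rank")], 5)
#>   feature kbest_rank tree_rank perm_rank combined_rank
#> 1 B10              1         4       1             6
#> 2 B45              3         3       5.5          11.5
#> 3 B18              5         1       5.5          11.5
#> 4 B43              2         2       9            13
#> 5 B05              4         5       7            16

reduce_and_compare(scr$retained, rk, k = 5,
                   spec = classifier_spec("gaussian_naive_bayes"), seed = 15)
#> <bs_reduction> 5-feature panel: accuracy 100.0% vs full 100.0% (p = 0.585)

ftest_5x2cv(scr$retained, classifier_spec("gaussian_naive_bayes"),
            classifier_spec("dummy_stratified"), seed = 16)
#> <bs_ftest> gaussian_naive_bayes vs dummy_stratified: F(10, 5) = 58.630, p = 0.0001506
```

Reading the output: 10 of the 50 simulated fingerprints were excluded by
the ESD screen (the generator injected liquid-handling failures at a 1%
per-well rate); the five classes are separated perfectly by nested CV; the
top five receptors of the combined ranking are all truly informative
(compare `panel$barrels$barrel_id[panel$barrels$informative]`); the
five-receptor mini-array performs indistinguishably from the full 46
(p = 0.585), while the real classifier beats the chance baseline decisively
(p = 1.5e-4).

Every result object has `tidy()` / `glance()` methods and most have
`autoplot()` (PCA projections, Spearman correlation heatmaps, confusion
matrices, ranking bars). `run_pipeline()` drives the whole chain from a
single JSON/YAML configuration and writes each stage's CSV/JSON artifacts.

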