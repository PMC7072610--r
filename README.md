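# immunometab

Baseline immune-metabolomic stratification of plasma samples, for
translational oncology and metabolomics researchers who work with two data
layers per patient: a binned ^1^H NMR (CPMG) plasma fingerprint and a panel
of circulating cytokines/metabolites. The package provides a tested,
reusable implementation of the full analysis chain — spectral bucketing
through classifier fusion — together with a synthetic cohort generator so
every stage can be exercised and validated without patient data.

## What it computes

**Spectral preparation.** Processed 1D spectra are integrated into
fixed-width chemical-shift buckets (default 0.2–10.00 ppm, 0.02 ppm wide),
buckets overlapping the residual-water and additive windows are discarded
(490 → 368 bins), and each sample is total-integral normalized
(`x_b / Σ_b x_b`).

**Multivariate classification (PCA–CA–kNN).** The normalized bucket matrix
is mean-centered and projected into an `n_pc`-dimensional PCA subspace;
canonical (Fisher) analysis finds the directions **w** maximizing the
between/within scatter ratio `wᵀB w / wᵀW w` (for two groups,
`w ∝ W⁻¹(m₁ − m₂)`); samples are classified by k-nearest-neighbour vote in
canonical-score space. Sensitivity, specificity and accuracy come from
leave-one-out cross-validation with the *whole* pipeline refitted per fold,
and significance from a permutation test with the add-one estimator
`p = (#{null ≥ observed} + 1)/(n_perm + 1)`. Loading analysis back-projects
the first canonical direction into bucket space to name the discriminating
ppm regions.

**Univariate screening.** Per feature: Wilcoxon–Mann–Whitney (exact for
small untied samples), Benjamini–Hochberg q-values, Cliff's delta
`δ = (#{x>y} − #{x<y})/(n₁n₂)` with the 0.147/0.33/0.474 magnitude
convention, and rank-based AUROC (so `|δ| = |2·AUROC − 1|` exactly).

**Fusion.** Two-feature weighted combinations `w₁z₁ + w₂z₂`
(`|w₁|+|w₂| = 1`, features z-scored and oriented toward the positive
class), weighted by an AUROC-maximizing grid scan or two-feature LDA, with
a Youden-optimal threshold; and a "logic OR" combination of two
classifiers (positive if either calls positive), summarized by a confusion
table.

**Cohort tables.** Pearson chi-square (no continuity correction) for
categorical arm comparisons, pooled/Welch t-tests from raw values or
printed summaries.

## Worked example

Everything below runs on a synthetic cohort with the package's reference
design: 21/22 samples per estrogen-receptor arm, arm-dependent fold effects
in five lipoprotein/creatinine ppm windows, response- and relapse-linked
analyte shifts, and 38% TNF-α dropout in one arm.

```r
library(immunometab)

cohort      <- generate_cohort(default_cohort_spec(), seed = 42)
fingerprint <- total_integral_normalize(cohort$matrix)

# 1. can the fingerprint separate the arms?
cv <- loocv(fingerprint, cohort$meta$er_status, n_pc = 3, k = 5, positive = "ER+")
cv
#> <cv_report: loocv> sensitivity 77.3%, specificity 90.5%, accuracy 83.7% (positive = ER+)

permutation_test(fingerprint, cohort$meta$er_status, n_pc = 3, k = 5,
                 n_perm = 1000, seed = 42, positive = "ER+")
#> <perm_test> observed LOOCV accuracy 0.837, p = 0.000999 (1000 permutations)
```

The out-of-fold accuracy (83.7%) beats all 1000 permuted-label refits, so
the arm separation is real (p = 1/1001). Which spectral regions carry it?

```r
model <- fit_pcaca_knn(fingerprint, cohort$meta$er_status, n_pc = 3, k = 5)
head(loading_analysis(model, fingerprint, cohort$meta$er_status), 5)
#> # A tibble: 5 × 5
#>   feature   center weight  rank higher_in
#>   <chr>      <dbl>  <dbl> <int> <chr>
#> 1 bin_1.250   1.25 -0.576     1 ER+
#> 2 bin_1.270   1.27 -0.448     2 ER+
#> 3 bin_1.290   1.29 -0.411     3 ER+
#> 4 bin_1.310   1.31 -0.292     4 ER+
#> 5 bin_1.330   1.33 -0.204     5 ER+
```

The top-ranked buckets sit in the 1.23–1.37 ppm lipid window that the
generator spiked, higher in the ER-positive arm — the loading analysis
recovers the planted truth. Univariate screening of the analyte panel
within the ER-positive arm:

```r
erp   <- subset(cohort$meta, er_status == "ER+")$sample_id
stats <- screen_markers(cohort$analytes[cohort$analytes$sample_id %in% erp, ],
                        cohort$meta, "response", positive = "GR")
head(stats, 3)
#> # A tibble: 3 × 9
#>   feature    n1    n2 u_statistic p_value q_value cliffs_delta delta_magnitude
#> 1 valine     11    11          20 0.00862  0.0679       -0.669 large
#> 2 alanine    11    11          21 0.0104   0.0679       -0.653 large
#> 3 TNFa       11    11          96 0.0215   0.0934        0.587 large
```

Valine is lower (δ < 0) and TNF-α higher (δ > 0) in complete responders, as
designed. Fusing the two into one score:

```r
dat <- dplyr::left_join(cohort$analytes, cohort$meta, by = "sample_id")
fusion <- fit_linear_combo(subset(dat, er_status == "ER+"),
                           c("TNFa", "valine"), "response", "GR")
fusion
#> <fusion_model: grid> 39.0% TNFa + 61.0% valine, threshold 0.304, AUROC 0.860 (positive = GR)
glance(fusion)[, c("auroc", "cv_auroc", "sensitivity", "specificity", "accuracy")]
#> # A tibble: 1 × 5
#>   auroc cv_auroc sensitivity specificity accuracy
#> 1 0.860    0.785       0.727           1    0.864
```

The combination improves on either marker alone; both the resubstitution
AUROC (0.86) and the honest leave-one-out rescored AUROC (0.79) are
reported. Finally, OR-fusion of a cytokine relapse model with the
metabolomics classifier:

```r
rel    <- subset(dat, er_status == "ER+")
combo  <- fit_linear_combo(rel, c("IL2", "IL10"), "relapse", "yes")
fp_erp <- fingerprint[fingerprint$sample_id %in% erp, ]
met    <- tibble::tibble(sample_id = fp_erp$sample_id,
                         pred = loocv(fp_erp, rel$relapse, n_pc = 3, k = 5,
                                      positive = "yes")$per_sample$pred)
cyt    <- score_linear_combo(combo, rel)[, c("sample_id", "pred")]
or_cal <- logic_or_predict(cyt, met, positive = "yes")
confusion(or_cal$pred, rel$relapse, positive = "yes")
#> # A tibble: 1 × 7
#>      tp    fp    tn    fn sensitivity specificity accuracy
#> 1     8     3    11     0           1       0.786    0.864
```

Every planted relapse is detected (sensitivity 1), at the cost of three
false positives — the characteristic OR-fusion trade: sensitivity can only
rise, specificity can only fall.

`run_full_analysis()` chains all of the above for one contrast from an
`analysis_config()` and writes a JSON + CSV report bundle;
`autoplot()`/`plot_loadings()`/`plot_roc()` draw the standard score,
loading and ROC figures.

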