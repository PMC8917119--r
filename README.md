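# astigzone

Residual-astigmatism prediction-error analysis for cataract surgery, across
keratometry measurement zones.

## The problem

After cataract surgery with a nontoric monofocal intraocular lens (IOL), the
crystalline lens no longer contributes astigmatism, so the postoperative
manifest refractive astigmatism essentially *is* the eye's total corneal
astigmatism (CA). That makes such cohorts a clean test bed for asking how well
anterior keratometry predicts total CA — and in particular whether the
**measurement zone** matters: some optical biometers project two concentric
mire rings (2.4 mm and 3.3 mm) and return both keratometry readings
simultaneously, removing device design as a confounder.

`astigzone` implements the full analysis pipeline for this question, for
clinician-scientists and IOL-formula developers:

1. **Vector algebra.** An astigmatism of magnitude `C` (D) at steep meridian
   `θ` is mapped to double-angle space, `(x, y) = (C cos 2θ, C sin 2θ)`, where
   astigmatism composes as ordinary 2-D vectors. Left eyes are mirrored
   (`θ′ = 180° − θ`) before pooling.
2. **Prediction.** Predicted residual astigmatism = anterior keratometric CA
   ⊕ posterior-cornea model (⊕ cohort-mean surgically induced astigmatism,
   SIA, when predicting from preoperative keratometry). The posterior corneal
   astigmatism (PCA) step is a pluggable model (`pca_zero()`,
   `pca_fixed_atr()`, `pca_proportional()`); every report states which model
   was used, since proprietary toric calculators cannot be embedded.
3. **Error statistics.** Per-eye prediction error `= actual − predicted` in
   double-angle space; centroid ± root-sum-square SD, mean absolute error,
   95% confidence ellipses of the dataset and of the centroid
   (chi-square-scaled eigen-decomposition of the 2×2 covariance), cumulative
   magnitude tables, paired between-zone *t* tests per component, subtype
   subgroups (with-the-rule 60–120°, against-the-rule 0–30°/150–180°, oblique
   otherwise), and OLS covariate screens.
4. **Synthetic cohorts.** A calibrated generator emulating a 101-eye
   dual-zone biometry cohort (with ground truth kept in a sidecar) so the
   whole pipeline is testable end to end by parameter recovery, without
   patient data.

## Worked example

```r
library(astigzone)

cfg <- analysis_config(generator = generator_config(n_eyes = 101, seed = 42))
bundle <- run_analysis(cfg)
bundle
#> <report_bundle>
#>   eyes: 101  zones: 2.4, 3.3  paths: preop_sia, postop_k
#>   PCA model: fixed_atr
#>   [preop_sia] 2.4 mm centroid 0.02 D @ 98° (±0.80), MAE 0.68 D
#>   [preop_sia] 3.3 mm centroid 0.01 D @ 108° (±0.79), MAE 0.68 D
#>   [postop_k] 2.4 mm centroid 0.02 D @ 98° (±0.69), MAE 0.61 D
#>   [postop_k] 3.3 mm centroid 0.01 D @ 108° (±0.71), MAE 0.62 D
```

Each line is one zone × prediction path: the centroid (vector-mean) error as
magnitude @ axis with its combined SD, and the mean absolute error (MAE).
Centroids near zero with MAE ≈ 0.6 D say the predictions are unbiased but
individually scattered; the preoperative-keratometry-plus-SIA path is noisier
than predicting from postoperative keratometry, as expected since it stacks
two measurement epochs and an SIA estimate.

Drill into the postoperative-path subgroup table and paired zone tests:

```r
s <- bundle$table3$postop_k$summaries
s[s$group %in% c("Total", "ATR"), ]
#>   group zone   n centroid_magnitude centroid_axis combined_sd mean_abs
#> 1 Total  2.4 101             0.0249          97.6       0.688    0.607
#> 2 Total  3.3 101             0.0107         107.9       0.706    0.618
#> 3   ATR  2.4  33             0.1459         108.8       0.704    0.630
#> 4   ATR  3.3  37             0.1239         111.3       0.744    0.646

bundle$table3$postop_k$comparisons[, c("group", "n", "mean_diff_x", "p_x", "p_y")]
#>     group   n mean_diff_x   p_x   p_y
#> 1   Total 101    -0.01533 0.451 0.992
#> 2     WTR  44    -0.01139 0.724 0.164
#> 3     ATR  31    -0.00369 0.929 0.772
#> 4 OBLIQUE  14    -0.05102 0.184 0.437
```

With the generator's default (zone-symmetric) noise model the two zones are
statistically indistinguishable — the paired *t* tests are correctly null.
The cohort-mean SIA estimate used by the preoperative path is in
`bundle$sia`, and `bundle$figures` holds double-angle ggplots (points,
centroid, red centroid ellipse, blue dataset ellipse) per zone and subgroup;
`analysis_config(output_dir = ...)` writes everything as CSV, markdown and
SVG. A thin command-line wrapper lives at `inst/cli/astigzone.R`
(`simulate`, `analyze`, `--version`).

To analyze a real cohort instead, prepare a CSV in the layout documented by
`cohort_schema()` (also shipped as `inst/extdata/cohort_schema.csv`) and pass
`analysis_config(input = "cohort.csv")`.

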