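---
title: "Methods: zone-wise astigmatism prediction-error analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zone-wise astigmatism prediction-error analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astigzone)
```

## The model

Clinical astigmatism is a magnitude–axis pair `(C, θ)` with `C ≥ 0` diopters
and `θ ∈ [0°, 180°)`, but axes are directionless meridians: 2° and 178° are
nearly the same astigmatism, and naively averaging axes is meaningless. The
standard remedy is the double-angle transform

\[ x = C\cos 2\theta, \qquad y = C\sin 2\theta, \]

which maps astigmatism onto a plane where it composes and averages as an
ordinary 2-D vector. Every statistic in this package — surgically induced
astigmatism (SIA), prediction errors, centroids, SDs, ellipses, *t* tests —
is computed on `(x, y)`; only presentation converts back to `(C, θ)` via
`C = √(x² + y²)`, `θ = ½·atan2(y, x) mod 180°`. The zero vector gets the
canonical axis 0°. Left eyes are mirror images of right eyes, so all polar
quantities of OS eyes are reflected (`θ′ = 180° − θ`) before pooling; in the
double-angle plane this is exactly `y ↦ −y`, so it preserves x-centroids and
negates y-centroids, an identity the tests exploit.

### Prediction of residual astigmatism

In eyes with a nontoric monofocal IOL, lenticular astigmatism is gone and
residual refractive astigmatism ≈ total corneal astigmatism. Predicted total
CA is assembled in double-angle space as

\[ \hat T = A + P(A) + S, \]

where `A` is the anterior keratometric CA (steep K − flat K at the steep
axis), `P(·)` a posterior-cornea (PCA) model, and `S` a SIA term that is
*only* included when predicting from preoperative keratometry — postoperative
keratometry already contains the incision's effect, so `S = 0` there and
supplying one is a usage error. `S` is the *cohort-mean* SIA vector (one
centroid per zone, left eyes mirrored first), not a per-eye value: per-eye
pre/post differences are dominated by measurement noise, and applying the
mean is how astigmatism planning is actually done.

The achieved ("actual") astigmatism is the postoperative manifest refraction
propagated to the corneal plane — each principal power `P ↦ P/(1 − dP)`,
vertex distance `d = 12 mm` by default (a configurable convention; manifest
refractions rarely record it) — then read as magnitude `|cyl|` with steep
meridian 90° from the minus-cylinder axis. The per-eye prediction error is

\[ e = T_{\text{actual}} - \hat T \]

in double-angle components. The sign convention (actual − predicted) is a
package convention, stated here because the literature rarely states one; all
paired comparisons are invariant to a global sign flip. A positive `x`
means the outcome was more against-the-rule than predicted.

### The PCA model is pluggable, on purpose

The posterior corneal surface contributes net against-the-rule astigmatism
that anterior keratometry cannot see. The widely used toric calculators
embed proprietary, unpublished PCA regressions, which cannot be reproduced
or redistributed. Rather than approximating one silently, the package makes
the PCA step an explicit object (`pca_zero()`, `pca_fixed_atr(magnitude)`,
`pca_proportional(scale, orientation)`) and every report prints which model
produced the predictions. Defaults (0.30 D fixed ATR; proportional scale
0.3) are round literature-consensus magnitudes, i.e. modelling choices of
this package. Consequently the package does **not** claim to reproduce any
published cohort's absolute centroid values obtained with a proprietary
calculator; what it does claim — and tests — is the correctness and
calibration of the vector analysis around whatever PCA model is chosen.

## Statistics

* **Centroid ± SD.** Component means with sample (n−1) SDs. The scalar "SD"
  attached to a centroid is the root-sum-square `√(sd_x² + sd_y²)`; this
  definition is the one consistent with the way combined SDs are printed in
  the clinical literature (e.g. an x-SD of 0.489 D and a combined 0.68 D
  imply a y-SD of ≈ 0.47 D). The mean absolute error `mean |e|` ≥ centroid
  magnitude always (triangle inequality); the gap is the axis-cancellation
  information the centroid preserves.
* **Confidence ellipses.** Eigen-decomposition of the 2×2 sample covariance;
  dataset ellipse semi-axes `√(q λᵢ)` with `q = χ²₂(0.95) = 5.991`, centroid
  ellipse scaled by a further `1/√n`. This is the convention of the common
  double-angle plotting tools. The small-sample Hotelling-T² scaling
  `2(n−1)/(n−2)·F(2, n−2)` is available via `scaling = "hotelling"`; at
  n = 101 the difference is under 5%. A rank-deficient covariance returns a
  flagged degenerate ellipse rather than an error, so plots of coincident
  points still render.
* **Zone comparison.** Two-sided paired *t* tests on x-components,
  y-components, and magnitudes, matching the component-wise way zone
  differences are reported clinically; no Hotelling joint test in the
  default report, and no multiple-testing correction (the report footnote
  says so). Zero within-pair variance yields `NA` p-values with a
  degeneracy flag instead of a spurious certainty.
* **Subgroups.** WTR `[60°, 120°]` (closed — clinical convention centers WTR
  on 90°), ATR `[0°, 30°) ∪ (150°, 180°)`, oblique the rest, so 30° and 150°
  are oblique; the boundary assignment at the shared endpoints is this
  package's deterministic choice, documented because published rules list
  overlapping closed ranges. An exhaustive 0–179° sweep (61/59/60 labels)
  pins the partition in the tests. Labels come from the preoperative CA axis
  at the zone under analysis; zero-magnitude CA is flagged since its axis is
  physically meaningless. When the two zones classify an eye differently,
  per-zone summaries use each zone's own label and paired subgroup
  comparisons use only label-concordant eyes, with the discordant count
  reported — the alternative (forcing one zone's label on both) silently
  mixes subtypes in one arm.
* **Covariate screen.** OLS (`stats::lm`) of the chosen error response
  (absolute error or either component — all three offered, since which one a
  given study regressed is often unstated) on age, sex, axial length, IOL
  power, preoperative astigmatism and corneal irregularity, univariately and
  multivariately; a design-matrix condition number above 1e8 attaches a
  collinearity warning.

## The synthetic cohort generator

The generator (`generator_config()`, `generate_cohort()`) emulates the
structure of a retrospective dual-zone biometry cohort so the pipeline can be
validated by parameter recovery. Defaults describe 101 eyes: age
68.7 ± 9.3 y truncated to 47–89, axial length 24.7 ± 2.0 mm (21.86–30.25),
IOL power 18.1 ± 5.2 D (6–27.5), anterior CA magnitude 0.7 ± 0.5 D truncated
to 0.05–2.05 D, subtype mix 46.5/32.7/20.8% WTR/ATR/oblique, 44.6% left
eyes, 24.8% second eyes (101 eyes ↦ 76 patients), incision at 145°, and a
2.4-mm zone reading steeper mean K by 0.04 D preoperatively / 0.08 D
postoperatively.

Axis scatter is wrapped-normal on the *doubled* angle around the subtype
center (90° WTR; 0° ATR; 45°/135° split evenly for oblique — the doubled
geometry makes these single points), keeping all randomness in the same
plane as the statistics and making centroids analytically known. The doubled
SD defaults to 15° (7.5° of axis scatter): this keeps the realized subtype
mix of classified axes within a few percent of the drawn mix, whereas wider
scatter bleeds oblique mass into the neighbouring bands. Truncated normals
are drawn by inverse-CDF so generation is deterministic given the seed
(`withr::with_seed`; draw order is fixed and documented in the source).

Measurement is modelled as: true CA vector + iid N(0, `k_noise_sd` = 0.15 D)
per double-angle component and zone, re-expressed as flat/steep K around a
noisy zone mean-K level (`mean_k_noise_sd` = 0.05 D) carrying the zone
offset; the manifest refraction as total CA (anterior ⊕ posterior ⊕ SIA) +
iid N(0, `refraction_noise_sd` = 0.45 D) per component, written as a
minus-cylinder sphero-cylinder at the spectacle plane through the inverse
vertex transform. These two noise knobs give prediction-error component SDs
of `√(0.15² + 0.45²) ≈ 0.47 D`, the order observed in real dual-zone
cohorts; refraction noise dominating keratometry noise reflects subjective
refraction's 0.25-D quantization and IOL tilt/decentration. The systematic
SIA defaults to 0.10 D with steep axis 55° (flattening at the 145° incision)
with 0.25 D per-component scatter — published per-eye SIA statistics for
2.65-mm clear corneal incisions are scarce, so these are explicit modelling
choices. Left-eye rows are stored with every axis mirrored (as a device
would record them), so the reader-side mirror must undo it — closing the
loop on the mirroring logic.

What the generator does *not* emulate: BCVA-driven exclusions (it emits only
analysis-eligible eyes; the filter logic is tested on hand-built fixtures),
within-patient correlation of fellow eyes (the analysis, like the clinical
practice it mirrors, treats eyes as independent), irregular astigmatism,
tear-film or accommodation drift, and any realistic coupling between
covariates and error (covariates are drawn independently, which is precisely
what makes the null covariate screen a calibration test). Passing tests on
synthetic cohorts therefore demonstrate the *correctness and calibration* of
the machinery, not the clinical magnitude of zone effects in real eyes.

## Numerical and design choices

* Axes are degrees everywhere in the public interface, half-open `[0, 180)`,
  with 180 canonicalized to 0; radians exist only inside trigonometry calls.
* Round-trips `polar → (x, y) → polar` are exact to 1e−9 D / 1e−7°, and the
  cohort CSV round-trips numerically at 6-decimal precision.
* Cylinder convention on disk may be plus or minus; memory is always
  minus-cylinder (plus rows are transposed on read).
* BCVA is stored as decimal acuity; the 20/30 inclusion floor is encoded as
  decimal ≥ 0.67 (Snellen fraction rounded to two decimals).
* Exclusion rules are applied in a fixed order (BCVA, prior surgery,
  complication, opacity) and each eye is counted against the first rule that
  removes it, so retained + excluded always totals the input even when flags
  overlap; per-sub-reason splits inside the BCVA rule are not modelled
  because chart-review sub-reasons are not part of the data contract.
* Degenerate inputs fail loudly and early (vergence singularity in the
  vertex transform, steep K below flat K, n < 2 SDs, n < 3 ellipses,
  mismatched pairing) or return flagged results where a plot must still
  render.
* Figures are SVG via the cairo `grDevices::svg()` device; tables CSV plus
  markdown. Determinism is guaranteed (and tested) at the data level — a
  re-run with the same configuration reproduces identical tables and per-eye
  records, from which figures re-render.

## Problem sizes in the test suite

The suite validates calibration at sizes chosen to keep the full run around
twenty seconds while leaving Monte-Carlo error well inside the asserted
bands: 10⁴ random draws for round-trip and loop-oracle equivalence, 2000
replicates of n = 101 for ellipse coverage (dataset ellipse 95% ± 1.5%,
centroid ellipse 95% ± 2% — the slight undercoverage of the χ² convention at
n = 101 sits inside these bands, which is exactly why the Hotelling option
exists), 1000 replicates for the paired-*t* size check (band 3.6–6.4%,
the 99% binomial interval), and n = 1000 single cohorts for 3·SE parameter
recovery of mean SIA and subtype-specific systematic errors.

## Known limitations

* No proprietary-calculator PCA reproduction (see above) — absolute
  centroids from studies using such calculators are out of reach by design.
* Eyes are treated as independent even when fellow eyes share a patient; a
  mixed-model extension would be needed to relax this.
* The corneal-plane conversion assumes a single vertex distance for all
  eyes.
* The generator's SIA and PCA truths are simple parametric models; they span
  the estimands the pipeline must recover, not the full physiological
  variability of corneal wound healing.
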