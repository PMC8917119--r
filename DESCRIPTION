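Package: astigzone
Title: Zone-Wise Corneal Astigmatism Prediction-Error Analysis for
    Cataract Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Vector analysis of residual-astigmatism prediction error after
    cataract surgery with nontoric monofocal intraocular lenses, comparing
    keratometry taken at two mire-ring diameter zones (2.4 mm and 3.3 mm) of
    the same optical biometer.  Implements polar-to-double-angle astigmatism
    algebra, the left-eye mirror transform, surgically induced astigmatism
    (SIA) centroids, pluggable posterior-corneal-astigmatism models,
    corneal-plane refraction conversion, centroid and mean-absolute-error
    summaries with 95% confidence ellipses of the dataset and of the
    centroid, cumulative-magnitude tables, paired zone comparisons and
    subgroup analyses by astigmatism type (with-the-rule, against-the-rule,
    oblique), covariate regression, double-angle plots, and a calibrated
    synthetic-cohort generator for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
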