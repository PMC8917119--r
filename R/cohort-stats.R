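#' Centroid summary of double-angle error vectors
#'
#' The centroid (component-wise mean) keeps magnitude *and* axis
#' information: opposite-axis errors cancel, which the mean absolute error
#' hides.  Component SDs use the sample (n - 1) denominator.  The scalar
#' "centroid +/- SD" dispersion is the root-sum-square of the two component
#' SDs, and the mean absolute error is the mean of the vector magnitudes,
#' which always bounds the centroid magnitude from above.
#'
#' @param x,y Double-angle components (diopters), equal length, `n >= 2`.
#' @return One-row tibble: `n`, `mean_x`, `mean_y`, `sd_x`, `sd_y`,
#'   `centroid_magnitude`, `centroid_axis`, `combined_sd`, `mean_abs`,
#'   `sd_abs`.
#' @export
#' @examples
#' centroid_summary(c(1, -1), c(0, 0))  # cancelling pair
centroid_summary <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("centroid summary requires n >= 2 (SD undefined below)", call. = FALSE)
  polar <- from_double_angle(mean(x), mean(y))
  mags <- sqrt(x^2 + y^2)
  tibble::tibble(
    n = n,
    mean_x = mean(x), mean_y = mean(y),
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    centroid_magnitude = polar$magnitude,
    centroid_axis = polar$axis,
    combined_sd = sqrt(stats::sd(x)^2 + stats::sd(y)^2),
    mean_abs = mean(mags),
    sd_abs = stats::sd(mags))
}

#' 95% confidence ellipse of a double-angle point cloud
#'
#' Eigen-decomposes the 2x2 sample covariance.  The *dataset* ellipse has
#' semi-axes `sqrt(q * lambda_i)` with `q` the chi-square(2) quantile at
#' `level` (5.991 at 0.95) and describes where individual eyes fall; the
#' *centroid* ellipse shrinks the same shape by `1/sqrt(n)` and describes
#' the uncertainty of the mean.  `scaling = "hotelling"` swaps the
#' chi-square quantile for the small-sample Hotelling T-squared F-scaling
#' `2 (n - 1) / (n - 2) * qf(level, 2, n - 2)`; at n = 101 the two differ
#' by under 5%.
#'
#' @param x,y Double-angle components (diopters), `n >= 3`.
#' @param level Confidence level (default 0.95).
#' @param kind `"dataset"` or `"centroid"`.
#' @param scaling `"chisq"` (default) or `"hotelling"`.
#' @return One-row tibble: `center_x`, `center_y`, `semi_major`,
#'   `semi_minor`, `orientation` (degrees in the double-angle plane,
#'   `[0, 180)`), `level`, `kind`, `n`, `degenerate`.
#' @export
confidence_ellipse <- function(x, y, level = 0.95,
                               kind = c("dataset", "centroid"),
                               scaling = c("chisq", "hotelling")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("confidence ellipse requires n >= 3", call. = FALSE)
  S <- stats::cov(cbind(x, y))
  eig <- eigen(S, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  q <- if (scaling == "chisq") stats::qchisq(level, df = 2)
       else 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2)
  semi <- sqrt(q * lambda)
  if (kind == "centroid") semi <- semi / sqrt(n)
  degenerate <- lambda[2] <= .Machine$double.eps * max(lambda[1], 1)
  orientation <- normalize_axis(atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi)
  tibble::tibble(center_x = mean(x), center_y = mean(y),
                 semi_major = semi[1], semi_minor = semi[2],
                 orientation = orientation, level = level, kind = kind,
                 n = n, degenerate = degenerate)
}

#' Points on a confidence ellipse outline
#'
#' @param ellipse One-row tibble from [confidence_ellipse()].
#' @param n_points Number of outline points.
#' @return Tibble with `x`, `y` tracing the ellipse (closed).
#' @export
ellipse_outline <- function(ellipse, n_points = 181) {
  t <- seq(0, 2 * pi, length.out = n_points)
  phi <- ellipse$orientation * pi / 180
  ex <- ellipse$semi_major * cos(t)
  ey <- ellipse$semi_minor * sin(t)
  tibble::tibble(x = ellipse$center_x + ex * cos(phi) - ey * sin(phi),
                 y = ellipse$center_y + ex * sin(phi) + ey * cos(phi))
}

#' Cumulative counts of astigmatism magnitudes at fixed thresholds
#'
#' @param values Magnitudes in diopters.
#' @param thresholds Ascending thresholds in diopters
#'   (default `c(0.5, 1, 1.5, 2)`).
#' @return Tibble with `threshold`, `n_le` (count `<= threshold`), and
#'   `proportion`; counts are monotone non-decreasing.
#' @export
#' @examples
#' cumulative_magnitude_table(c(0.3, 0.6, 1.2))
cumulative_magnitude_table <- function(values, thresholds = c(0.5, 1, 1.5, 2)) {
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  n_le <- vapply(thresholds, function(t) sum(values <= t), integer(1))
  tibble::tibble(threshold = thresholds, n_le = n_le,
                 proportion = if (length(values) == 0) rep(0, length(thresholds))
                              else n_le / length(values))
}

#' Paired comparison of prediction errors between two zones
#'
#' Two-sided paired t tests on the x-components, the y-components, and the
#' vector magnitudes of per-eye errors measured at two zones in the same
#' eyes (same order).  With zero within-pair variance the t statistic is
#' undefined; the mean differences are still reported and `degenerate` is
#' set.
#'
#' @param errors_a,errors_b Data frames with columns `x`, `y`, one row per
#'   eye, identically ordered.
#' @return One-row tibble: `n`, `mean_diff_x`, `mean_diff_y`, `p_x`, `p_y`,
#'   `mean_diff_abs`, `p_abs`, `degenerate`.
#' @export
paired_zone_comparison <- function(errors_a, errors_b) {
  if (nrow(errors_a) != nrow(errors_b)) {
    stop("paired comparison needs the same eyes in the same order", call. = FALSE)
  }
  n <- nrow(errors_a)
  if (n < 2) stop("paired comparison requires n >= 2", call. = FALSE)
  abs_a <- sqrt(errors_a$x^2 + errors_a$y^2)
  abs_b <- sqrt(errors_b$x^2 + errors_b$y^2)
  paired_p <- function(d) {
    if (stats::sd(d) == 0) NA_real_
    else stats::t.test(d)$p.value
  }
  dx <- errors_a$x - errors_b$x
  dy <- errors_a$y - errors_b$y
  da <- abs_a - abs_b
  tibble::tibble(n = n,
                 mean_diff_x = mean(dx), mean_diff_y = mean(dy),
                 p_x = paired_p(dx), p_y = paired_p(dy),
                 mean_diff_abs = mean(da), p_abs = paired_p(da),
                 degenerate = stats::sd(dx) == 0 || stats::sd(dy) == 0 ||
                   stats::sd(da) == 0)
}

#' Per-subtype centroid summaries and between-zone comparisons
#'
#' Splits prediction records by astigmatism subtype (WTR/ATR/oblique, from
#' the preoperative CA axis at each zone) and reports, per zone, the
#' centroid summary for every subtype plus the overall cohort, and the
#' paired between-zone comparison within each group.  Because the two
#' zones can classify the same eye differently, per-zone summaries use
#' each zone's own label, while paired comparisons use only eyes whose
#' labels agree across zones; the discordant count is reported.
#'
#' @param records Tibble of [prediction_records()] rows for exactly two
#'   zones of the same eyes and path.
#' @return List with `summaries` (tibble: `group`, `zone`, centroid-summary
#'   columns), `comparisons` (tibble: `group` plus
#'   [paired_zone_comparison()] columns), `discordant_n`, and `dropped`
#'   (groups too small to summarize).
#' @export
subgroup_analysis <- function(records) {
  zones <- sort(unique(records$zone))
  if (length(zones) != 2) stop("subgroup_analysis expects records from exactly two zones",
                               call. = FALSE)
  groups <- c("Total", levels(records$subtype))
  summaries <- list(); comparisons <- list(); dropped <- character()
  a <- records[records$zone == zones[1], ]
  b <- records[records$zone == zones[2], ]
  b <- b[match(a$eye_id, b$eye_id), ]
  if (anyNA(b$eye_id)) stop("the two zones cover different eyes", call. = FALSE)
  discordant_n <- sum(as.character(a$subtype) != as.character(b$subtype))
  for (g in groups) {
    for (zi in seq_along(zones)) {
      r <- records[records$zone == zones[zi], ]
      if (g != "Total") r <- r[as.character(r$subtype) == g, ]
      if (nrow(r) < 2) { dropped <- union(dropped, g); next }
      s <- centroid_summary(r$error_x, r$error_y)
      summaries[[length(summaries) + 1]] <-
        dplyr::bind_cols(tibble::tibble(group = g, zone = zones[zi]), s)
    }
    sel <- if (g == "Total") rep(TRUE, nrow(a))
           else as.character(a$subtype) == g & as.character(b$subtype) == g
    if (sum(sel) >= 2) {
      cmp <- paired_zone_comparison(
        tibble::tibble(x = a$error_x[sel], y = a$error_y[sel]),
        tibble::tibble(x = b$error_x[sel], y = b$error_y[sel]))
      comparisons[[length(comparisons) + 1]] <-
        dplyr::bind_cols(tibble::tibble(group = g), cmp)
    } else {
      dropped <- union(dropped, g)
    }
  }
  list(summaries = dplyr::bind_rows(summaries),
       comparisons = dplyr::bind_rows(comparisons),
       discordant_n = discordant_n,
       dropped = dropped)
}

#' Ordinary least squares screen of prediction-error covariates
#'
#' Regresses a per-eye error response on clinical covariates, either all
#' at once (`mode = "multivariate"`) or one covariate at a time
#' (`mode = "univariate"`).  No multiple-testing correction is applied;
#' report readers should treat the p-values as exploratory.
#'
#' @param data Tibble with the response column and covariate columns.
#' @param response Name of the response column (e.g. `"abs_error"`,
#'   `"error_x"`, `"error_y"`).
#' @param covariates Character vector of covariate column names.
#' @param mode `"multivariate"` (default) or `"univariate"`.
#' @param condition_limit Design-matrix condition number above which a
#'   collinearity warning is recorded (default 1e8).
#' @return Tibble with `model`, `term`, `estimate`, `std_error`,
#'   `p_value`, `n`; attribute `collinearity_warning` (character, possibly
#'   empty).
#' @export
covariate_regression <- function(data, response,
                                 covariates = c("age", "sex", "axial_length",
                                                "iol_power", "preop_astigmatism",
                                                "corneal_irregularity"),
                                 mode = c("multivariate", "univariate"),
                                 condition_limit = 1e8) {
  mode <- match.arg(mode)
  covariates <- intersect(covariates, names(data))
  if (length(covariates) == 0) stop("no requested covariate is present", call. = FALSE)
  if (nrow(data) <= length(covariates) + 2) {
    stop("too few rows for the requested model", call. = FALSE)
  }
  fit_one <- function(terms, label) {
    f <- stats::reformulate(terms, response = response)
    fit <- stats::lm(f, data = data)
    co <- summary(fit)$coefficients
    tibble::tibble(model = label, term = rownames(co),
                   estimate = unname(co[, 1]), std_error = unname(co[, 2]),
                   p_value = unname(co[, 4]), n = stats::nobs(fit))
  }
  warn <- character()
  if (mode == "multivariate") {
    out <- fit_one(covariates, "multivariate")
    mm <- stats::model.matrix(stats::reformulate(covariates), data = data)
    if (kappa(mm) > condition_limit) {
      warn <- sprintf("design matrix condition number %.3g exceeds %.3g",
                      kappa(mm), condition_limit)
    }
  } else {
    out <- dplyr::bind_rows(lapply(covariates, function(cv) fit_one(cv, cv)))
  }
  attr(out, "collinearity_warning") <- warn
  out
}
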