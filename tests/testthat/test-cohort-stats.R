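test_that("centroid summary matches hand arithmetic on degenerate clouds", {
  s <- centroid_summary(c(1, -1), c(0, 0))
  expect_equal(s$mean_x, 0)
  expect_equal(s$centroid_magnitude, 0)
  expect_equal(s$mean_abs, 1)
  expect_equal(s$sd_x, sqrt(2))
  expect_equal(s$combined_sd, sqrt(2))
  v <- centroid_summary(rep(0.3, 5), rep(0.4, 5))
  expect_equal(v$centroid_magnitude, 0.5)
  expect_equal(v$sd_x, 0)
  expect_equal(v$sd_y, 0)
  expect_equal(v$mean_abs, 0.5)
  expect_error(centroid_summary(1, 1), "n >= 2")
})

test_that("a centroid of (0.058, 0.069) prints as 0.09 D near 25 degrees", {
  p <- from_double_angle(0.058, 0.069)
  expect_equal(round(p$magnitude, 2), 0.09)
  expect_equal(round(p$axis), 25)
})

test_that("centroid summary agrees with an explicit loop oracle", {
  withr::local_seed(12)
  x <- rnorm(1e4); y <- rnorm(1e4)
  s <- centroid_summary(x, y)
  n <- length(x)
  sx <- 0; sy <- 0; sa <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]; sa <- sa + sqrt(x[i]^2 + y[i]^2)
  }
  mx <- sx / n; my <- sy / n
  vx <- 0; vy <- 0
  for (i in seq_len(n)) {
    vx <- vx + (x[i] - mx)^2; vy <- vy + (y[i] - my)^2
  }
  expect_equal(s$mean_x, mx, tolerance = 1e-12)
  expect_equal(s$mean_y, my, tolerance = 1e-12)
  expect_equal(s$sd_x, sqrt(vx / (n - 1)), tolerance = 1e-12)
  expect_equal(s$sd_y, sqrt(vy / (n - 1)), tolerance = 1e-12)
  expect_equal(s$mean_abs, sa / n, tolerance = 1e-12)
  expect_true(s$mean_abs >= s$centroid_magnitude)
})

test_that("the root-sum-square combined SD is compatible with printed summaries", {
  # combined 0.68 with x-SD 0.489 implies a y-SD inside (0.45, 0.49)
  sd_y <- sqrt(0.68^2 - 0.489^2)
  expect_gt(sd_y, 0.45)
  expect_lt(sd_y, 0.49)
  s <- centroid_summary(c(-1, 0, 1), c(-2, 0, 2))
  expect_equal(s$combined_sd, sqrt(s$sd_x^2 + s$sd_y^2))
})

test_that("confidence ellipses have closed-form axes for unit isotropic covariance", {
  a <- sqrt(1.5)  # four points with exact identity sample covariance
  x <- c(a, -a, 0, 0); y <- c(0, 0, a, -a)
  e <- confidence_ellipse(x, y, 0.95, "dataset")
  expect_equal(e$semi_major, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_equal(e$semi_minor, sqrt(qchisq(0.95, 2)), tolerance = 1e-9)
  expect_false(e$degenerate)

  b <- sqrt(99 / 50)  # 100 points, identity covariance
  x <- c(rep(b, 25), rep(-b, 25), rep(0, 50))
  y <- c(rep(0, 50), rep(b, 25), rep(-b, 25))
  e <- confidence_ellipse(x, y, 0.95, "centroid")
  expect_equal(e$semi_major, sqrt(qchisq(0.95, 2)) / 10, tolerance = 1e-9)
  expect_equal(e$n, 100)
})

test_that("coincident points give a flagged degenerate ellipse", {
  e <- confidence_ellipse(rep(1, 5), rep(2, 5), 0.95, "dataset")
  expect_true(e$degenerate)
  expect_equal(e$semi_major, 0)
  expect_equal(e$semi_minor, 0)
  expect_error(confidence_ellipse(1:2, 1:2), "n >= 3")
})

test_that("Hotelling scaling widens the centroid ellipse at small n", {
  withr::local_seed(8)
  x <- rnorm(20); y <- rnorm(20)
  chi <- confidence_ellipse(x, y, 0.95, "centroid", scaling = "chisq")
  hot <- confidence_ellipse(x, y, 0.95, "centroid", scaling = "hotelling")
  expect_gt(hot$semi_major, chi$semi_major)
  expect_equal(hot$orientation, chi$orientation)
})

test_that("ellipse outlines lie on the ellipse boundary", {
  withr::local_seed(9)
  x <- rnorm(50, 1, 2); y <- 0.4 * x + rnorm(50, -1, 0.5)
  e <- confidence_ellipse(x, y, 0.95, "dataset")
  pts <- ellipse_outline(e, 73)
  phi <- e$orientation * pi / 180
  dx <- pts$x - e$center_x; dy <- pts$y - e$center_y
  u <- (dx * cos(phi) + dy * sin(phi)) / e$semi_major
  v <- (-dx * sin(phi) + dy * cos(phi)) / e$semi_minor
  expect_equal(u^2 + v^2, rep(1, 73), tolerance = 1e-9)
})

test_that("cumulative magnitude tables count values at or below each threshold", {
  t <- cumulative_magnitude_table(c(0.3, 0.6, 1.2), c(0.5, 1.0, 1.5))
  expect_equal(t$n_le, c(1L, 2L, 3L))
  expect_true(all(diff(t$n_le) >= 0))
  expect_equal(cumulative_magnitude_table(numeric(0), c(0.5, 1))$n_le, c(0L, 0L))
  full <- cumulative_magnitude_table(c(0.1, 0.2), c(0.5, 1))
  expect_equal(full$n_le, c(2L, 2L))
  expect_equal(full$proportion, c(1, 1))
  expect_error(cumulative_magnitude_table(1, c(1, 0.5)), "ascending")
})

test_that("cumulative counts agree with a loop oracle on random data", {
  withr::local_seed(21)
  vals <- runif(1e4, 0, 2.5)
  th <- sort(runif(6, 0, 2.5))
  t <- cumulative_magnitude_table(vals, th)
  for (j in seq_along(th)) {
    cnt <- 0L
    for (v in vals) if (v <= th[j]) cnt <- cnt + 1L
    expect_identical(t$n_le[j], cnt)
  }
})

test_that("paired zone comparison reports mean differences and p-values", {
  withr::local_seed(30)
  a <- tibble::tibble(x = rnorm(40), y = rnorm(40))
  same <- paired_zone_comparison(a, a)
  expect_equal(same$mean_diff_x, 0)
  expect_true(same$degenerate)
  expect_true(is.na(same$p_x))
  b <- tibble::tibble(x = a$x - 0.4 + rnorm(40, 0, 0.1), y = a$y + rnorm(40, 0, 0.1))
  cmp <- paired_zone_comparison(a, b)
  expect_equal(cmp$mean_diff_x, mean(a$x - b$x))
  expect_equal(cmp$p_x, t.test(a$x, b$x, paired = TRUE)$p.value)
  expect_lt(cmp$p_x, 0.001)
  expect_error(paired_zone_comparison(a, b[1:10, ]), "same eyes")
})

test_that("subgroup analysis reduces to the global analysis when one type is present", {
  # noiseless keratometry so measured subtype labels equal the drawn ones
  gen <- generate_cohort(generator_config(
    n_eyes = 30, seed = 5, subtype_weights = c(WTR = 1, ATR = 0, OBLIQUE = 0),
    k_noise_sd = 0, mean_k_noise_sd = 0))
  rec <- dplyr::bind_rows(
    prediction_records(gen$cohort, 2.4, "postop_k"),
    prediction_records(gen$cohort, 3.3, "postop_k"))
  sg <- subgroup_analysis(rec)
  tot <- sg$summaries[sg$summaries$group == "Total", ]
  wtr <- sg$summaries[sg$summaries$group == "WTR", ]
  expect_equal(tot$centroid_magnitude, wtr$centroid_magnitude)
  expect_equal(tot$n, wtr$n)
  expect_true(all(c("ATR", "OBLIQUE") %in% sg$dropped))
  # per-zone subtype counts partition the cohort
  for (z in c(2.4, 3.3)) {
    by_type <- sg$summaries[sg$summaries$zone == z & sg$summaries$group != "Total", ]
    expect_equal(sum(by_type$n), 30)
  }
})

test_that("covariate regression recovers exact linear structure", {
  withr::local_seed(77)
  d <- tibble::tibble(age = runif(60, 50, 90), axial_length = rnorm(60, 24, 2))
  d$abs_error <- 2 * d$age
  fit <- suppressWarnings(  # summary.lm warns on a perfect fit
    covariate_regression(d, "abs_error", c("age", "axial_length")))
  age_row <- fit[fit$term == "age", ]
  expect_equal(age_row$estimate, 2, tolerance = 1e-8)
  expect_lt(age_row$p_value, 1e-10)
  # constant response: slopes are exactly zero
  d$abs_error <- 1.5
  fit0 <- suppressWarnings(
    covariate_regression(d, "abs_error", c("age", "axial_length")))
  expect_equal(fit0$estimate[fit0$term != "(Intercept)"], c(0, 0),
               tolerance = 1e-12)
  # univariate mode fits one model per covariate
  d$abs_error <- 2 * d$age + rnorm(60)
  uni <- covariate_regression(d, "abs_error", c("age", "axial_length"),
                              mode = "univariate")
  expect_setequal(unique(uni$model), c("age", "axial_length"))
})

test_that("collinear designs are flagged", {
  withr::local_seed(78)
  d <- tibble::tibble(age = runif(40, 50, 90))
  d$age2 <- d$age * (1 + 1e-12)
  d$abs_error <- rnorm(40)
  fit <- covariate_regression(d, "abs_error", c("age", "age2"))
  expect_gt(length(attr(fit, "collinearity_warning")), 0)
})
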