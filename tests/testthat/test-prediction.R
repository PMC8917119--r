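test_that("vertex propagation transforms each principal power as P/(1 - dP)", {
  expect_equal(refraction_to_corneal_plane(0, 0, 0),
               tibble::tibble(sphere = 0, cylinder = 0, axis = 0))
  r <- refraction_to_corneal_plane(-2.5, -0.75, 40, vertex_distance = 0)
  expect_equal(r, tibble::tibble(sphere = -2.5, cylinder = -0.75, axis = 40))
  r <- refraction_to_corneal_plane(-4, -1, 180, vertex_distance = 0.012)
  expect_equal(round(r$sphere, 3), -3.817)
  expect_equal(round(r$cylinder, 3), -0.900)
  expect_equal(r$axis, 0)
  expect_error(refraction_to_corneal_plane(90, 0, 0, 0.012), "singularity")
})

test_that("refractive astigmatism reads the steep meridian off the minus-cyl axis", {
  expect_equal(refractive_astigmatism(0, -1, 180),
               tibble::tibble(magnitude = 1, axis = 90))
  expect_equal(refractive_astigmatism(-2, 0, 35),
               tibble::tibble(magnitude = 0, axis = 0))
  # plus-cylinder input is transposed first
  expect_equal(refractive_astigmatism(0, 1, 90),
               tibble::tibble(magnitude = 1, axis = 90))
})

test_that("SIA is the double-angle change from preop to postop CA", {
  expect_equal(sia_vector(0.8, 30, 0.8, 30), tibble::tibble(x = 0, y = 0),
               tolerance = 1e-12)
  flip <- sia_vector(1, 90, 1, 0)
  expect_equal(flip$x, 2)
  expect_equal(flip$y, 0, tolerance = 1e-12)
  steepen <- sia_vector(0.5, 90, 0.7, 90)
  expect_equal(steepen$x, -0.2)
  expect_equal(steepen$y, 0, tolerance = 1e-12)
})

test_that("mean SIA is the centroid of per-eye SIA vectors", {
  one <- manual_eye("E1", pre24 = c(43, 44, 90), post24 = c(43, 44, 0),
                    pre33 = c(43, 44, 90), post33 = c(43, 44, 0))
  m <- mean_sia(one, 2.4)
  expect_equal(c(m$x, m$y), c(2, 0), tolerance = 1e-12)
  expect_equal(m$n, 1)
  # equal and opposite per-eye SIA cancels
  two <- manual_cohort(
    manual_eye("E1", pre24 = c(43, 44, 90), post24 = c(43, 45, 90)),
    manual_eye("E2", pre24 = c(43, 45, 90), post24 = c(43, 44, 90)))
  m <- mean_sia(two, 2.4)
  expect_equal(c(m$x, m$y), c(0, 0), tolerance = 1e-12)
})

test_that("predicted residual astigmatism composes anterior CA, PCA and SIA", {
  eye <- manual_eye("E1", post24 = c(43.2, 44.0, 95))
  p <- predict_residual(eye, 2.4, "postop_k", pca = pca_zero())
  expect_equal(p$pred_magnitude, 0.8)
  expect_equal(p$pred_axis, 95)
  # a 0.30 D ATR posterior exactly cancels a 0.30 D WTR anterior
  eye <- manual_eye("E1", post24 = c(43.7, 44.0, 90))
  p <- predict_residual(eye, 2.4, "postop_k", pca = pca_fixed_atr(0.30))
  expect_equal(p$pred_magnitude, 0, tolerance = 1e-12)
  # preop path with zero SIA is the postop-path formula applied to preop K
  eye <- manual_eye("E1", pre24 = c(43.1, 44.3, 40), post24 = c(43.0, 43.5, 170))
  a <- predict_residual(eye, 2.4, "preop_sia", pca = pca_fixed_atr(0.2),
                        sia = c(0, 0))
  eye_swap <- manual_eye("E1", pre24 = c(43.1, 44.3, 40),
                         post24 = c(43.1, 44.3, 40))
  b <- predict_residual(eye_swap, 2.4, "postop_k", pca = pca_fixed_atr(0.2))
  expect_equal(a$pred_magnitude, b$pred_magnitude)
  expect_equal(a$pred_axis, b$pred_axis)
})

test_that("the SIA argument is enforced per prediction path", {
  eye <- manual_eye("E1")
  expect_error(predict_residual(eye, 2.4, "postop_k", sia = c(0.1, 0)),
               "postop_k")
  expect_error(predict_residual(eye, 2.4, "preop_sia"), "SIA")
})

test_that("preop-with-SIA and postop paths agree when postop K is preop plus that SIA", {
  sia <- to_double_angle(0.35, 55)
  pre <- to_double_angle(1.1, 80)
  post <- from_double_angle(pre$x + sia$x, pre$y + sia$y)
  eye <- manual_eye("E1",
                    pre24 = c(43, 43 + 1.1, 80),
                    post24 = c(43, 43 + post$magnitude, post$axis))
  a <- predict_residual(eye, 2.4, "preop_sia", pca = pca_fixed_atr(0.3),
                        sia = c(sia$x, sia$y))
  b <- predict_residual(eye, 2.4, "postop_k", pca = pca_fixed_atr(0.3))
  expect_equal(a$pred_magnitude, b$pred_magnitude, tolerance = 1e-9)
  expect_equal(a$pred_axis, b$pred_axis, tolerance = 1e-7)
})

test_that("prediction error is actual minus predicted, translation-consistent", {
  expect_equal(prediction_error(0.8, 95, 0.8, 95), tibble::tibble(x = 0, y = 0),
               tolerance = 1e-12)
  e <- prediction_error(0, 0, 0.5, 0)
  expect_equal(c(e$x, e$y), c(0.5, 0), tolerance = 1e-12)
  # antisymmetry
  ab <- prediction_error(1.2, 30, 0.4, 110)
  ba <- prediction_error(0.4, 110, 1.2, 30)
  expect_equal(ab$x, -ba$x)
  expect_equal(ab$y, -ba$y)
  # translating both by the same double-angle vector leaves the error unchanged
  withr::local_seed(5)
  for (i in 1:20) {
    p <- c(runif(1, 0, 2), runif(1, 0, 180))
    a <- c(runif(1, 0, 2), runif(1, 0, 180))
    v <- rnorm(2, 0, 0.5)
    base <- prediction_error(p[1], p[2], a[1], a[2])
    pd <- to_double_angle(p[1], p[2]); ad <- to_double_angle(a[1], a[2])
    p2 <- from_double_angle(pd$x + v[1], pd$y + v[2])
    a2 <- from_double_angle(ad$x + v[1], ad$y + v[2])
    shifted <- prediction_error(p2$magnitude, p2$axis, a2$magnitude, a2$axis)
    expect_equal(c(shifted$x, shifted$y), c(base$x, base$y), tolerance = 1e-9)
  }
})

test_that("the PCA model catalogue provides zero, fixed-ATR and proportional models", {
  z <- predict(pca_zero(), c(0.5, 2), c(10, 100))
  expect_equal(z, tibble::tibble(x = c(0, 0), y = c(0, 0)))
  f <- predict(pca_fixed_atr(0.30), c(0.5, 2), c(10, 100))
  expect_equal(f$x, c(0.30, 0.30))
  expect_equal(f$y, c(0, 0), tolerance = 1e-12)
  p <- predict(pca_proportional(0.3, orientation = 0), 1.0, 90)
  expect_equal(sqrt(p$x^2 + p$y^2), 0.30)
  al <- predict(pca_proportional(0.5, orientation = "anterior"), 1.0, 70)
  expect_equal(from_double_angle(al$x, al$y),
               tibble::tibble(magnitude = 0.5, axis = 70), tolerance = 1e-9)
  expect_equal(pca_model("zero")$name, "zero")
  expect_error(pca_model("quadratic"), "unknown PCA model")
})

test_that("per-eye records close the loop when actual equals predicted", {
  # actual refraction constructed so its corneal-plane astigmatism equals the
  # anterior CA; with a zero PCA model every error must vanish
  eyes <- manual_cohort(
    manual_eye("E1", laterality = "OD", post24 = c(43.0, 43.9, 75),
               ref = ref_for_corneal_astig(0.9, 75)),
    manual_eye("E2", laterality = "OS", post24 = c(43.2, 44.0, 130),
               ref = ref_for_corneal_astig(0.8, 130)))
  rec <- prediction_records(eyes, 2.4, "postop_k", pca = pca_zero())
  expect_equal(rec$error_x, c(0, 0), tolerance = 1e-9)
  expect_equal(rec$error_y, c(0, 0), tolerance = 1e-9)
  expect_equal(rec$abs_error, c(0, 0), tolerance = 1e-9)
})

test_that("left eyes are mirrored consistently on both sides of the error", {
  # same physical eye data recorded OD vs OS (mirrored axes) must give
  # mirrored errors: x equal, y negated
  od <- manual_eye("E1", laterality = "OD", pre24 = c(43, 44, 30),
                   post24 = c(43, 44.2, 40), ref = ref_for_corneal_astig(1.0, 60))
  os <- manual_eye("E2", laterality = "OS", pre24 = c(43, 44, 150),
                   post24 = c(43, 44.2, 140), ref = ref_for_corneal_astig(1.0, 120))
  rec <- prediction_records(dplyr::bind_rows(od, os), 2.4, "postop_k",
                            pca = pca_fixed_atr(0.25))
  expect_equal(rec$error_x[1], rec$error_x[2], tolerance = 1e-9)
  expect_equal(rec$error_y[1], rec$error_y[2], tolerance = 1e-9)
  expect_equal(rec$abs_error[1], rec$abs_error[2], tolerance = 1e-9)
})
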