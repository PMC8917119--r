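#' Propagate a sphero-cylinder refraction to the corneal plane
#'
#' Each principal power `P` at the spectacle plane becomes
#' `P / (1 - d P)` at the cornea, with `d` the vertex distance in metres.
#' The result is re-expressed in minus-cylinder form; meridian axes are
#' unchanged by the propagation.
#'
#' @param sphere,cylinder Minus-cylinder sphero-cylinder, diopters
#'   (plus-cylinder input is transposed first).
#' @param axis Cylinder axis, degrees.
#' @param vertex_distance Spectacle-to-cornea distance in metres
#'   (default 0.012).
#' @return Tibble with `sphere`, `cylinder`, `axis` at the corneal plane.
#' @export
#' @examples
#' refraction_to_corneal_plane(-4, -1, 180)  # -3.817 / -0.900 x 180
refraction_to_corneal_plane <- function(sphere, cylinder, axis,
                                        vertex_distance = 0.012) {
  r <- as_minus_cylinder(sphere, cylinder, axis)
  p1 <- r$sphere
  p2 <- r$sphere + r$cylinder
  if (any(1 - vertex_distance * c(p1, p2) <= 0, na.rm = TRUE)) {
    stop("vergence singularity: |power| must stay below 1/vertex_distance",
         call. = FALSE)
  }
  q1 <- p1 / (1 - vertex_distance * p1)
  q2 <- p2 / (1 - vertex_distance * p2)
  tibble::tibble(sphere = q1, cylinder = q2 - q1, axis = r$axis)
}

# inverse propagation (cornea -> spectacle), used by the cohort generator
refraction_to_spectacle_plane <- function(sphere, cylinder, axis,
                                          vertex_distance = 0.012) {
  r <- as_minus_cylinder(sphere, cylinder, axis)
  p1 <- r$sphere
  p2 <- r$sphere + r$cylinder
  q1 <- p1 / (1 + vertex_distance * p1)
  q2 <- p2 / (1 + vertex_distance * p2)
  tibble::tibble(sphere = q1, cylinder = q2 - q1, axis = r$axis)
}

#' Refractive astigmatism of a sphero-cylinder
#'
#' The magnitude is the absolute cylinder; the steep meridian sits 90
#' degrees from the minus-cylinder axis (which marks the flat meridian).
#'
#' @inheritParams refraction_to_corneal_plane
#' @return Tibble with `magnitude` (D) and `axis` (steep meridian, degrees).
#' @export
#' @examples
#' refractive_astigmatism(0, -1, 180)  # 1 D @ 90
refractive_astigmatism <- function(sphere, cylinder, axis) {
  r <- as_minus_cylinder(sphere, cylinder, axis)
  tibble::tibble(magnitude = abs(r$cylinder),
                 axis = ifelse(r$cylinder == 0, 0, normalize_axis(r$axis + 90)))
}

#' Surgically induced astigmatism vector
#'
#' The double-angle difference between postoperative and preoperative
#' corneal astigmatism of the same eye and measurement zone.
#'
#' @param preop_magnitude,preop_axis Preoperative CA (polar form).
#' @param postop_magnitude,postop_axis Postoperative CA (polar form).
#' @return Tibble with double-angle components `x`, `y` (diopters).
#' @export
#' @examples
#' sia_vector(1, 90, 1, 0)  # (2, 0): full WTR-to-ATR flip
sia_vector <- function(preop_magnitude, preop_axis, postop_magnitude, postop_axis) {
  double_angle_subtract(to_double_angle(postop_magnitude, postop_axis),
                        to_double_angle(preop_magnitude, preop_axis))
}

# keratometric CA at one zone/epoch, with OS axes mirrored into OD frame
zone_ca <- function(cohort, zone, epoch = c("preop", "postop"), mirror = TRUE) {
  epoch <- match.arg(epoch)
  suffix <- zone_suffix(zone)
  ca <- keratometric_astigmatism(
    cohort[[paste0(epoch, "_flat_k_", suffix)]],
    cohort[[paste0(epoch, "_steep_k_", suffix)]],
    cohort[[paste0(epoch, "_steep_axis_", suffix)]])
  if (mirror) {
    os <- cohort$laterality == "OS"
    ca$axis[os] <- mirror_axis(ca$axis[os])
  }
  ca
}

zone_suffix <- function(zone) {
  s <- c("2.4" = "24", "3.3" = "33")[as.character(zone)]
  if (is.na(s)) stop("zone must be 2.4 or 3.3", call. = FALSE)
  s
}

#' Cohort-mean surgically induced astigmatism at a zone
#'
#' Per-eye SIA vectors (left eyes mirrored first) averaged component-wise
#' in double-angle space — the single centroid SIA that the
#' preoperative-keratometry prediction path applies to every eye.
#'
#' @param cohort Cohort tibble.
#' @param zone Measurement zone, 2.4 or 3.3 (mm).
#' @return One-row tibble with `x`, `y` (diopters) and `n`.
#' @export
mean_sia <- function(cohort, zone) {
  if (nrow(cohort) < 1) stop("mean SIA requires at least one eye", call. = FALSE)
  pre <- zone_ca(cohort, zone, "preop")
  post <- zone_ca(cohort, zone, "postop")
  s <- sia_vector(pre$magnitude, pre$axis, post$magnitude, post$axis)
  tibble::tibble(x = mean(s$x), y = mean(s$y), n = nrow(cohort))
}

#' Predicted residual astigmatism for every eye of a cohort
#'
#' With a nontoric monofocal IOL the cornea is essentially the eye's only
#' astigmatic element, so the predicted total corneal astigmatism *is* the
#' predicted residual refractive astigmatism at the corneal plane.  Two
#' prediction paths are supported:
#'
#' * `"postop_k"` — postoperative keratometry plus the PCA model; the
#'   incision's effect is already in the measurement, so no SIA term is
#'   allowed;
#' * `"preop_sia"` — preoperative keratometry plus the PCA model plus a
#'   supplied cohort-mean SIA vector (see [mean_sia()]).
#'
#' Left-eye axes are mirrored before composition, so predictions are in
#' the pooled right-eye frame.
#'
#' @param cohort Cohort tibble.
#' @param zone Measurement zone, 2.4 or 3.3 (mm).
#' @param path `"postop_k"` or `"preop_sia"`.
#' @param pca A [pca_model()] (default [pca_zero()]).
#' @param sia Cohort-mean SIA as a data frame with `x`, `y` or a numeric
#'   length-2 vector; required for `"preop_sia"`, forbidden for
#'   `"postop_k"`.
#' @return Tibble with `eye_id`, `zone`, `path`, `pred_magnitude`,
#'   `pred_axis`.
#' @export
predict_residual <- function(cohort, zone, path = c("postop_k", "preop_sia"),
                             pca = pca_zero(), sia = NULL) {
  path <- match.arg(path)
  if (path == "postop_k" && !is.null(sia)) {
    stop("SIA must not be supplied on the postop_k path ",
         "(the incision effect is already in the postoperative keratometry)",
         call. = FALSE)
  }
  if (path == "preop_sia" && is.null(sia)) {
    stop("the preop_sia path requires a cohort-mean SIA vector (see mean_sia())",
         call. = FALSE)
  }
  anterior <- zone_ca(cohort, zone, if (path == "postop_k") "postop" else "preop")
  v <- to_double_angle(anterior$magnitude, anterior$axis)
  v <- double_angle_add(v, predict(pca, anterior$magnitude, anterior$axis))
  if (path == "preop_sia") {
    sia <- as_xy(sia)
    v$x <- v$x + sia[1]
    v$y <- v$y + sia[2]
  }
  polar <- from_double_angle(v$x, v$y)
  tibble::tibble(eye_id = cohort$eye_id, zone = zone, path = path,
                 pred_magnitude = polar$magnitude, pred_axis = polar$axis)
}

as_xy <- function(v) {
  if (is.data.frame(v)) c(v$x[1], v$y[1]) else {
    stopifnot(is.numeric(v), length(v) == 2)
    as.numeric(v)
  }
}

#' Astigmatism prediction error in double-angle space
#'
#' `error = actual - predicted`, component-wise in double-angle space; a
#' positive x-component means the outcome was more against-the-rule
#' (equivalently, less with-the-rule) than predicted.  Both inputs must
#' already be in the pooled (mirrored) frame.
#'
#' @param pred_magnitude,pred_axis Predicted residual astigmatism (polar).
#' @param actual_magnitude,actual_axis Achieved refractive astigmatism at
#'   the corneal plane (polar).
#' @return Tibble with `x`, `y` (diopters).
#' @export
prediction_error <- function(pred_magnitude, pred_axis,
                             actual_magnitude, actual_axis) {
  double_angle_subtract(to_double_angle(actual_magnitude, actual_axis),
                        to_double_angle(pred_magnitude, pred_axis))
}

#' Per-eye prediction records for one zone and path
#'
#' Runs the whole per-eye pipeline: keratometric CA extraction, left-eye
#' mirroring, PCA-model adjustment (and SIA on the preoperative path),
#' corneal-plane conversion of the manifest refraction, and the
#' double-angle prediction error.  Astigmatism subtype labels come from
#' the preoperative CA axis at the same zone (mirrored frame); eyes with
#' zero preoperative CA are flagged since orientation is then meaningless.
#'
#' @inheritParams predict_residual
#' @param vertex_distance Metres (default 0.012) for the corneal-plane
#'   conversion of the manifest refraction.
#' @return Tibble with one row per eye: identifiers, predicted and actual
#'   polar astigmatism, `error_x`, `error_y`, `abs_error`, `subtype`,
#'   `zero_preop_ca`.
#' @export
prediction_records <- function(cohort, zone, path = c("postop_k", "preop_sia"),
                               pca = pca_zero(), sia = NULL,
                               vertex_distance = 0.012) {
  path <- match.arg(path)
  pred <- predict_residual(cohort, zone, path, pca, sia)
  corneal <- refraction_to_corneal_plane(cohort$ref_sphere, cohort$ref_cylinder,
                                         cohort$ref_axis, vertex_distance)
  actual <- refractive_astigmatism(corneal$sphere, corneal$cylinder, corneal$axis)
  os <- cohort$laterality == "OS"
  actual$axis[os] <- mirror_axis(actual$axis[os])
  err <- prediction_error(pred$pred_magnitude, pred$pred_axis,
                          actual$magnitude, actual$axis)
  preop <- zone_ca(cohort, zone, "preop")
  tibble::tibble(
    eye_id = cohort$eye_id,
    laterality = cohort$laterality,
    zone = zone,
    path = path,
    pred_magnitude = pred$pred_magnitude,
    pred_axis = pred$pred_axis,
    actual_magnitude = actual$magnitude,
    actual_axis = actual$axis,
    error_x = err$x,
    error_y = err$y,
    abs_error = sqrt(err$x^2 + err$y^2),
    subtype = classify_astigmatism(preop$axis),
    zero_preop_ca = preop$magnitude == 0)
}
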