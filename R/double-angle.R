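#' Normalize a steep-meridian axis into [0, 180)
#'
#' Clinical axes are reported 0--180 degrees with 180 synonymous with 0.
#' This maps any angle (including negative values and exactly 180) onto the
#' canonical half-open interval.
#'
#' @param axis Numeric vector of axes in degrees.
#' @return Numeric vector in `[0, 180)`.
#' @export
#' @examples
#' normalize_axis(c(180, 190, -10))
normalize_axis <- function(axis) {
  axis %% 180
}

#' Convert polar astigmatism to double-angle Cartesian components
#'
#' An astigmatism of magnitude `C` diopters with steep meridian `theta`
#' degrees maps to the point `(C cos 2theta, C sin 2theta)` in double-angle
#' space, where astigmatism vectors add component-wise.  All cohort-level
#' averaging in this package happens in this space.
#'
#' @param magnitude Cylinder magnitude in diopters, `>= 0`.
#' @param axis Steep-meridian axis in degrees, `[0, 180)` (180 is accepted
#'   and normalized to 0).
#' @return A tibble with columns `x` and `y` (diopters).
#' @export
#' @examples
#' to_double_angle(0.09, 25)   # x component 0.058 D
#' to_double_angle(1, 90)      # (-1, 0)
to_double_angle <- function(magnitude, axis) {
  stopifnot(is.numeric(magnitude), is.numeric(axis))
  if (any(magnitude < 0, na.rm = TRUE)) {
    stop("astigmatism magnitude must be non-negative", call. = FALSE)
  }
  axis <- normalize_axis(axis)
  theta <- 2 * axis * pi / 180
  tibble::tibble(x = magnitude * cos(theta), y = magnitude * sin(theta))
}

#' Convert double-angle components back to polar astigmatism
#'
#' Inverse of [to_double_angle()].  The zero vector maps to the canonical
#' `0 D @ 0`.
#'
#' @param x,y Double-angle components in diopters.
#' @return A tibble with columns `magnitude` (D) and `axis` (degrees in
#'   `[0, 180)`).
#' @export
#' @examples
#' from_double_angle(-1, 0)  # 1 D @ 90
from_double_angle <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  magnitude <- sqrt(x^2 + y^2)
  axis <- normalize_axis(atan2(y, x) * 90 / pi)
  axis[magnitude == 0] <- 0
  tibble::tibble(magnitude = magnitude, axis = axis)
}

#' Mirror a left-eye axis into right-eye orientation
#'
#' Left (OS) and right (OD) eyes are approximate mirror images, so pooling
#' them requires reflecting OS axes: `axis' = (180 - axis) mod 180`
#' (magnitude unchanged).  Applied to every polar quantity of an OS eye
#' before any cohort-level statistic.
#'
#' @param axis Steep-meridian axis in degrees `[0, 180)`.
#' @return Mirrored axis in `[0, 180)`.  The transform is an involution.
#' @export
#' @examples
#' mirror_axis(30)  # 150
#' mirror_axis(90)  # fixed point
mirror_axis <- function(axis) {
  normalize_axis(180 - normalize_axis(axis))
}

#' Keratometric corneal astigmatism from a flat/steep K pair
#'
#' @param flat_k,steep_k Principal corneal powers in diopters
#'   (`steep_k >= flat_k`).
#' @param steep_axis Axis of the steep meridian, degrees.
#' @return A tibble with columns `magnitude` (`steep_k - flat_k`) and
#'   `axis` (the steep axis, normalized).
#' @export
#' @examples
#' keratometric_astigmatism(43.57, 44.27, 90)  # 0.70 D @ 90
keratometric_astigmatism <- function(flat_k, steep_k, steep_axis) {
  bad <- !is.na(flat_k) & !is.na(steep_k) & steep_k < flat_k
  if (any(bad)) {
    stop("steep K below flat K at position(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(magnitude = steep_k - flat_k, axis = normalize_axis(steep_axis))
}

#' Classify astigmatism orientation as WTR, ATR or oblique
#'
#' Steep meridian at 60--120 degrees is with-the-rule (WTR), 0--30 or
#' 150--180 against-the-rule (ATR), and 30--60 or 120--150 oblique.  The
#' shared endpoints are resolved deterministically: WTR takes the closed
#' interval `[60, 120]` (clinical convention centers WTR on 90), ATR takes
#' `[0, 30)` and `(150, 180)`, and oblique the remainder, so 30 and 150 are
#' oblique.
#'
#' @param axis Steep-meridian axis in degrees, must lie in `[0, 180)`.
#' @return Factor with levels `WTR`, `ATR`, `OBLIQUE`.
#' @export
#' @examples
#' classify_astigmatism(c(90, 10, 45, 30, 150))
classify_astigmatism <- function(axis) {
  if (any(axis < 0 | axis >= 180, na.rm = TRUE)) {
    stop("axis must lie in [0, 180)", call. = FALSE)
  }
  lab <- ifelse(axis >= 60 & axis <= 120, "WTR",
                ifelse(axis < 30 | axis > 150, "ATR", "OBLIQUE"))
  factor(lab, levels = c("WTR", "ATR", "OBLIQUE"))
}

#' Component-wise arithmetic on double-angle vectors
#'
#' All astigmatism composition (SIA application, posterior-cornea addition,
#' prediction-error subtraction) is ordinary vector arithmetic in
#' double-angle space.  `a` and `b` are data frames with `x`/`y` columns
#' (recycled row-wise if one has a single row).
#'
#' @param a,b Data frames with numeric columns `x` and `y` (diopters).
#' @return A tibble with columns `x`, `y`.
#' @export
#' @examples
#' double_angle_add(to_double_angle(1, 0), to_double_angle(1, 45))
double_angle_add <- function(a, b) {
  tibble::tibble(x = a$x + b$x, y = a$y + b$y)
}

#' @rdname double_angle_add
#' @export
double_angle_subtract <- function(a, b) {
  tibble::tibble(x = a$x - b$x, y = a$y - b$y)
}
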