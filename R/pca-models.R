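#' Pluggable posterior corneal astigmatism (PCA) models
#'
#' Anterior keratometry misses the back corneal surface, which on average
#' contributes net against-the-rule astigmatism at the total-power level.
#' Proprietary toric calculators embed an undisclosed PCA regression; this
#' package instead makes the PCA model an explicit, swappable component so
#' that every prediction states which model produced it.  Three built-in
#' models are provided:
#'
#' * `pca_zero()` — no adjustment (anterior keratometry taken as total CA);
#' * `pca_fixed_atr(magnitude)` — a constant vector of `magnitude` diopters
#'   with steep meridian at 180 (i.e. `(+magnitude, 0)` in double-angle
#'   space), the literature-consensus net-ATR contribution;
#' * `pca_proportional(scale, orientation)` — magnitude `scale` times the
#'   anterior magnitude, oriented at a fixed axis (degrees) or, with
#'   `orientation = "anterior"`, along the anterior steep meridian.
#'
#' All defaults are modelling choices of this package, not published
#' calculator constants.
#'
#' @param magnitude Constant PCA magnitude in diopters (default 0.30).
#' @param scale Proportionality constant (default 0.3).
#' @param orientation Steep-meridian axis in degrees, or `"anterior"`.
#' @return An object of class `pca_model`.
#' @name pca_models
#' @examples
#' predict(pca_fixed_atr(0.3), magnitude = 1, axis = 90)
NULL

new_pca_model <- function(name, parameters, fun) {
  structure(list(name = name, parameters = parameters, fun = fun),
            class = "pca_model")
}

#' @rdname pca_models
#' @export
pca_zero <- function() {
  new_pca_model("zero", list(),
                function(magnitude, axis) to_double_angle(rep(0, length(magnitude)),
                                                          rep(0, length(magnitude))))
}

#' @rdname pca_models
#' @export
pca_fixed_atr <- function(magnitude = 0.30) {
  stopifnot(is.numeric(magnitude), length(magnitude) == 1, magnitude >= 0)
  new_pca_model("fixed_atr", list(magnitude = magnitude),
                function(mag, axis) to_double_angle(rep(magnitude, length(mag)),
                                                    rep(0, length(mag))))
}

#' @rdname pca_models
#' @export
pca_proportional <- function(scale = 0.3, orientation = 0) {
  stopifnot(is.numeric(scale), length(scale) == 1, scale >= 0)
  fixed_axis <- !identical(orientation, "anterior")
  if (fixed_axis) stopifnot(is.numeric(orientation), length(orientation) == 1)
  new_pca_model("proportional",
                list(scale = scale, orientation = orientation),
                function(mag, axis) {
                  ax <- if (fixed_axis) rep(normalize_axis(orientation), length(mag)) else axis
                  to_double_angle(scale * mag, ax)
                })
}

#' Look up a built-in PCA model by name
#'
#' @param name One of `"zero"`, `"fixed_atr"`, `"proportional"`.
#' @param ... Passed to the model constructor.
#' @return A `pca_model`.
#' @export
pca_model <- function(name, ...) {
  switch(name,
         zero = pca_zero(),
         fixed_atr = pca_fixed_atr(...),
         proportional = pca_proportional(...),
         stop("unknown PCA model: '", name,
              "' (available: zero, fixed_atr, proportional)", call. = FALSE))
}

#' Predict the posterior corneal astigmatism contribution
#'
#' @param object A `pca_model`.
#' @param magnitude,axis Anterior corneal astigmatism (polar form).
#' @param ... Unused.
#' @return A tibble with double-angle components `x`, `y` of the modelled
#'   posterior contribution at the total-power level.
#' @export
predict.pca_model <- function(object, magnitude, axis, ...) {
  stopifnot(length(magnitude) == length(axis))
  object$fun(magnitude, axis)
}

#' @export
print.pca_model <- function(x, ...) {
  pars <- if (length(x$parameters) == 0) "" else
    paste0("(", paste(names(x$parameters), unlist(x$parameters), sep = " = ",
                      collapse = ", "), ")")
  cat("<pca_model> ", x$name, pars, "\n", sep = "")
  invisible(x)
}
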