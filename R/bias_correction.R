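# Age-dependent prediction-bias estimation and removal.
#
# Brain-age regressors systematically overestimate young and underestimate
# old subjects (regression to the mean). The residual (predicted - true)
# is smoothed against true age with LOWESS on validation-set predictions,
# and the LOWESS curve is parametrized by a cubic smoothing spline for fast
# evaluation; corrected age = raw age - bias(reference age), with constant
# extrapolation outside the validation age range.

#' Fit a prediction-bias model from validation predictions
#'
#' Smooths the residual `predicted - true` against true age with LOWESS
#' (fraction 0.3, 2 robustness iterations) and fits the resulting curve
#' with a cubic smoothing spline (smoothing parameter `spar = 0.1`).
#'
#' @param true_age Numeric vector of chronological ages (years); at least
#'   30 pairs are required for a stable curve.
#' @param predicted_age Numeric vector of raw (uncorrected) predicted
#'   ages.
#' @param structure_config Optional label of the structure configuration
#'   the model belongs to.
#' @param lowess_f LOWESS smoother span.
#' @param lowess_iter LOWESS robustness iterations.
#' @param spar Smoothing-spline parameter.
#' @return A `bias_model`: list with `spline`, `range` (valid age range),
#'   `lowess` (the smoothed sample points) and `structure_config`.
#' @export
#' @examples
#' a <- seq(50, 90, length.out = 100)
#' m <- fit_bias(a, a + 2)      # constant +2-year bias
#' predict_bias(m, 70)
fit_bias <- function(true_age, predicted_age, structure_config = NULL,
                     lowess_f = 0.3, lowess_iter = 2L, spar = 0.1) {
  if (length(true_age) != length(predicted_age))
    stop_strucage("length mismatch", class = "strucage_validation_error")
  keep <- stats::complete.cases(true_age, predicted_age)
  true_age <- true_age[keep]
  predicted_age <- predicted_age[keep]
  if (length(true_age) < 30L)
    stop_strucage("at least 30 validation pairs are required, got ",
                  length(true_age), class = "strucage_validation_error")
  resid <- predicted_age - true_age
  lw <- stats::lowess(true_age, resid, f = lowess_f, iter = lowess_iter)
  sp <- stats::smooth.spline(lw$x, lw$y, spar = spar)
  structure(list(spline = sp, range = range(true_age), lowess = lw,
                 structure_config = structure_config,
                 spar = spar, lowess_f = lowess_f),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("bias_model over ages [", round(x$range[1], 1), ",",
      round(x$range[2], 1), "]; bias at range ends:",
      round(predict_bias(x, x$range[1]), 2), "/",
      round(predict_bias(x, x$range[2]), 2), "years\n")
  invisible(x)
}

#' Evaluate the fitted bias curve
#'
#' @param model A [fit_bias()] model.
#' @param age Ages at which to evaluate (clamped to the model's valid
#'   range; extrapolation is constant).
#' @return Bias in years (positive = overestimation).
#' @export
predict_bias <- function(model, age) {
  if (!inherits(model, "bias_model"))
    stop_strucage("bias model is not fitted", class = "strucage_state_error")
  age <- pmin(pmax(age, model$range[1]), model$range[2])
  as.numeric(stats::predict(model$spline, age)$y)
}

#' Apply bias correction to age predictions
#'
#' Corrected age = raw aggregated age minus the bias evaluated at the
#' reference age. In deployment the reference defaults to the raw
#' predicted age itself (the true age is the quantity being estimated);
#' for evaluation-style plots against known ages, pass the true ages as
#' `reference_age`.
#'
#' @param model A [fit_bias()] model.
#' @param prediction An `age_prediction` from [predict_ensemble_tta()], or
#'   a numeric vector of raw predicted ages.
#' @param reference_age Optional ages at which to evaluate the bias;
#'   defaults to the raw predictions.
#' @return The `age_prediction` with `corrected` filled, or a numeric
#'   vector of corrected ages.
#' @export
apply_bias <- function(model, prediction, reference_age = NULL) {
  if (!inherits(model, "bias_model"))
    stop_strucage("bias model is not fitted", class = "strucage_state_error")
  raw <- if (inherits(prediction, "age_prediction")) prediction$aggregated
         else as.numeric(prediction)
  ref <- reference_age %||% raw
  corrected <- raw - predict_bias(model, ref)
  if (inherits(prediction, "age_prediction")) {
    prediction$corrected <- corrected
    prediction
  } else {
    corrected
  }
}
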