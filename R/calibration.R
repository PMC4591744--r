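## Linear calibration of renal dynamic imaging GFR to the dual plasma
## sample Tc-99m-DTPA clearance. The calibrated value is the "standard
## GFR" (sGFR) reference used throughout model development.

#' Fit a linear imaging-to-dual-plasma GFR calibration
#'
#' Ordinary least squares of dual-plasma GFR on renal dynamic imaging GFR
#' over paired measurements on the same subjects. (Errors-in-variables
#' alternatives such as Deming regression exist; plain OLS is the
#' convention for this calibration and is what is implemented.)
#'
#' @param imaging_gfr renal dynamic imaging GFR, mL/min/1.73 m^2 (> 0).
#' @param dual_plasma_gfr dual plasma sample GFR, mL/min/1.73 m^2 (> 0).
#' @return object of class `calibration_model` with fields `intercept`,
#'   `slope`, `r_squared`, `n`.
#' @export
fit_calibration <- function(imaging_gfr, dual_plasma_gfr) {
  stopifnot(length(imaging_gfr) == length(dual_plasma_gfr))
  n <- length(imaging_gfr)
  if (n < 3) abort_gfrdm("calibration needs at least 3 pairs", "gfrdm_insufficient_data_error")
  check_positive(imaging_gfr, "imaging_gfr")
  check_positive(dual_plasma_gfr, "dual_plasma_gfr")
  if (stats::sd(imaging_gfr) == 0) {
    abort_gfrdm("imaging GFR values are constant; calibration slope is undetermined",
                "gfrdm_degenerate_regression_error")
  }
  fit <- stats::lm(dual_plasma_gfr ~ imaging_gfr)
  cf <- stats::coef(fit)
  # suppressWarnings: summary.lm warns on exactly collinear (perfect-fit)
  # pairs, which are a legitimate input here
  calibration_model(intercept = cf[[1]], slope = cf[[2]],
                    r_squared = suppressWarnings(summary(fit)$r.squared), n = n)
}

#' @rdname fit_calibration
#' @param intercept,slope,r_squared,n components of a calibration model.
#' @export
calibration_model <- function(intercept, slope, r_squared = NA_real_, n = NA_integer_) {
  stopifnot(is.na(r_squared) || (r_squared >= 0 && r_squared <= 1 + 1e-12))
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r_squared, n = n),
            class = "calibration_model")
}

#' Built-in imaging GFR calibration
#'
#' The reference calibration of renal dynamic imaging GFR to the dual
#' plasma sample clearance, fitted on 36 type 2 diabetic subjects:
#' `dual-plasma GFR = 3.706 + 1.039 x imaging GFR` (R^2 = 0.879). Use
#' when no calibration pairs of your own are available.
#'
#' @return a [calibration_model()].
#' @export
dtpa_calibration <- function() {
  calibration_model(intercept = 3.706, slope = 1.039, r_squared = 0.879, n = 36L)
}

#' Apply a calibration to imaging GFR values
#'
#' @param model a [calibration_model()].
#' @param imaging_gfr imaging GFR value(s), mL/min/1.73 m^2 (>= 0).
#' @return standard GFR: `intercept + slope * imaging_gfr`.
#' @export
apply_calibration <- function(model, imaging_gfr) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(imaging_gfr < 0)) abort_gfrdm("imaging_gfr must be non-negative", "gfrdm_domain_error")
  model$intercept + model$slope * imaging_gfr
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> sGFR = %.3f + %.3f x imaging GFR (R^2 = %.3f, n = %s)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}
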