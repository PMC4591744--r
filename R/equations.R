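## Published creatinine-based eGFR comparator equations, plus evaluation of
## fitted two-slope log-spline equations. All GFRs are indexed to 1.73 m^2
## body surface area; no BSA re-normalization is performed.

is_female <- function(sex) {
  sex <- toupper(as.character(sex))
  bad <- !sex %in% c("F", "M")
  if (any(bad)) abort_validation(sprintf("sex must be F or M, got '%s'", sex[bad][1]))
  sex == "F"
}

check_positive <- function(x, what) {
  if (any(is.na(x) | x <= 0)) {
    abort_gfrdm(sprintf("%s must be positive", what), "gfrdm_domain_error")
  }
}

#' CKD-EPI creatinine equation
#'
#' Two-slope power law in serum creatinine with sex-specific knot
#' \eqn{\kappa} (0.7 mg/dL women, 0.9 mg/dL men):
#' \deqn{eGFR = 141 \times \min(Scr/\kappa, 1)^{\alpha} \times
#'   \max(Scr/\kappa, 1)^{-1.209} \times 0.993^{Age}
#'   \times 1.018 [female] \times 1.159 [black]}
#' The standard published exponents \eqn{\alpha = -0.329} (female) /
#' \eqn{-0.411} (male) are used by default. Some secondary sources print
#' \eqn{\alpha} with a positive sign, which would make eGFR *increase* with
#' creatinine below the knot; `as_printed = TRUE` reproduces that variant
#' for auditing transcriptions, but the negative-sign form is the equation.
#'
#' @param sex "F"/"M" (vectorized, recycled against the other arguments).
#' @param age years (>= 18 for the intended domain).
#' @param scr serum creatinine, mg/dL (> 0).
#' @param black logical race indicator; default `FALSE` (the 1.159 factor
#'   is retained for completeness).
#' @param as_printed use the positive-alpha transcription (audit only).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi("M", 60, 0.9)   # at the male knot: 141 * 0.993^60
#' @export
ckd_epi <- function(sex, age, scr, black = FALSE, as_printed = FALSE) {
  female <- is_female(sex)
  check_positive(scr, "scr")
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  if (as_printed) alpha <- -alpha
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
    0.993^age * ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' Japanese eGFR equation (creatinine power law)
#'
#' \deqn{eGFR = 194 \times Scr^{-1.094} \times Age^{-0.287} \times 0.739 [female]}
#'
#' @inheritParams ckd_epi
#' @return eGFR in mL/min/1.73 m^2.
#' @export
japanese_1 <- function(sex, age, scr) {
  female <- is_female(sex)
  check_positive(scr, "scr")
  check_positive(age, "age")
  194 * scr^-1.094 * age^-0.287 * ifelse(female, 0.739, 1)
}

#' Japanese eGFR equation with an HbA1c correction
#'
#' [japanese_1()] divided by \eqn{0.428 + 0.0085 \times HbA1c}, the
#' glycemia correction proposed for diabetic patients (after Tsuda).
#'
#' @inheritParams ckd_epi
#' @param hba1c glycated hemoglobin, percent (> 0).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
japanese_2 <- function(sex, age, scr, hba1c) {
  check_positive(hba1c, "hba1c")
  japanese_1(sex, age, scr) / (0.428 + 0.0085 * hba1c)
}

#' Two-slope log-spline eGFR equation model
#'
#' The fitted-equation form developed in this package: on the log scale,
#' eGFR is linear in `min(ln(Scr/kappa_sex), 0)` and
#' `max(ln(Scr/kappa_sex), 0)` (a continuous two-slope spline in log
#' creatinine with sex-specific knots, 0.7 mg/dL women / 0.8 mg/dL men by
#' default), plus age, a female indicator, and any of BMI / HbA1c / UACR on
#' the natural scale:
#' \deqn{\ln eGFR = b_0 + b_{<}\min(\ln(Scr/\kappa), 0) +
#'   b_{>}\max(\ln(Scr/\kappa), 0) + b_{age} Age + b_F [female] +
#'   \sum_k b_k x_k}
#'
#' @param intercept log-scale intercept.
#' @param slope_below,slope_above slopes in log creatinine below / above the
#'   sex knot.
#' @param age_coef per-year coefficient.
#' @param female_coef additive log-scale female term.
#' @param covariate_coefs named numeric vector with names among
#'   `bmi`, `hba1c`, `uacr` (per-natural-unit coefficients).
#' @param knot_female,knot_male creatinine knots, mg/dL.
#' @return object of class `spline_model`.
#' @examples
#' m <- spline_model(intercept = log(100), slope_below = 0, slope_above = 0)
#' predict(m, data.frame(sex = "M", age = 60, scr = 1.2))  # 100
#' @export
spline_model <- function(intercept, slope_below, slope_above,
                         age_coef = 0, female_coef = 0,
                         covariate_coefs = numeric(0),
                         knot_female = 0.7, knot_male = 0.8) {
  stopifnot(knot_female > 0, knot_male > 0)
  covariate_coefs <- unlist(covariate_coefs)
  if (length(covariate_coefs)) {
    bad <- setdiff(names(covariate_coefs), c("bmi", "hba1c", "uacr"))
    if (length(bad)) {
      abort_validation(sprintf("unknown covariate coefficient(s): %s", paste(bad, collapse = ", ")))
    }
  }
  structure(list(intercept = intercept, slope_below = slope_below,
                 slope_above = slope_above, age_coef = age_coef,
                 female_coef = female_coef,
                 covariate_coefs = covariate_coefs,
                 knot_female = knot_female, knot_male = knot_male),
            class = "spline_model")
}

#' Evaluate a two-slope log-spline equation on patient records
#'
#' @param object a [spline_model()].
#' @param newdata a `cohort` or data frame with `sex`, `age`, `scr` and any
#'   covariates the model names; a missing required covariate is an error.
#' @param ... unused.
#' @return eGFR vector, mL/min/1.73 m^2 (strictly positive).
#' @export
predict.spline_model <- function(object, newdata, ...) {
  female <- is_female(newdata$sex)
  check_positive(newdata$scr, "scr")
  kappa <- ifelse(female, object$knot_female, object$knot_male)
  ls <- log(newdata$scr / kappa)
  eta <- object$intercept +
    object$slope_below * pmin(ls, 0) +
    object$slope_above * pmax(ls, 0) +
    object$age_coef * newdata$age +
    object$female_coef * as.numeric(female)
  for (cov in names(object$covariate_coefs)) {
    x <- newdata[[cov]]
    if (is.null(x) || anyNA(x)) {
      abort_gfrdm(sprintf("model requires covariate '%s', absent or missing in the data", cov),
                  "gfrdm_evaluation_error")
    }
    eta <- eta + object$covariate_coefs[[cov]] * x
  }
  exp(eta)
}

#' @export
print.spline_model <- function(x, ...) {
  cat("<spline_model> ln(eGFR) =\n")
  cat(sprintf("  %+.5f %+.5f*min(ln(Scr/k),0) %+.5f*max(ln(Scr/k),0) %+.6f*Age %+.5f*[female]\n",
              x$intercept, x$slope_below, x$slope_above, x$age_coef, x$female_coef))
  for (cov in names(x$covariate_coefs)) {
    cat(sprintf("  %+.6f*%s\n", x$covariate_coefs[[cov]], cov))
  }
  cat(sprintf("  knots: %.2f (F) / %.2f (M) mg/dL\n", x$knot_female, x$knot_male))
  invisible(x)
}
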