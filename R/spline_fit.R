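## Development of the new regression equations: OLS of ln(sGFR) on the
## two-slope creatinine spline plus age, sex and the configured covariate
## set; BMI, HbA1c and UACR enter on the natural scale, creatinine and GFR
## on the natural-log scale.

#' The eight covariate sets used for equation / ANN development
#'
#' Every model includes age, sex and serum creatinine; the eight variable
#' sets add BMI, HbA1c and UACR separately and in combination:
#' eq1 none; eq2 HbA1c; eq3 BMI; eq4 UACR; eq5 HbA1c + BMI;
#' eq6 HbA1c + UACR; eq7 BMI + UACR; eq8 all three.
#'
#' @return named list mapping `eq1`..`eq8` to covariate name vectors.
#' @export
variable_sets <- function() {
  list(eq1 = character(0),
       eq2 = "hba1c",
       eq3 = "bmi",
       eq4 = "uacr",
       eq5 = c("hba1c", "bmi"),
       eq6 = c("hba1c", "uacr"),
       eq7 = c("bmi", "uacr"),
       eq8 = c("hba1c", "uacr", "bmi"))
}

resolve_vset <- function(vset) {
  if (is.character(vset) && length(vset) == 1 && grepl("^(eq|ann)[1-8]$", vset)) {
    return(variable_sets()[[sub("^ann", "eq", vset)]])
  }
  vset <- as.character(vset)
  bad <- setdiff(vset, c("bmi", "hba1c", "uacr"))
  if (length(bad)) abort_validation(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
  vset
}

spline_design <- function(cohort, covariates, knots) {
  female <- is_female(cohort$sex)
  kappa <- ifelse(female, knots[["female"]], knots[["male"]])
  ls <- log(cohort$scr / kappa)
  X <- cbind(scr_below = pmin(ls, 0), scr_above = pmax(ls, 0),
             age = cohort$age, female = as.numeric(female))
  for (cov in covariates) X <- cbind(X, cohort[[cov]])
  colnames(X) <- c("scr_below", "scr_above", "age", "female", covariates)
  X
}

#' Fit a two-slope log-spline eGFR equation by least squares
#'
#' Ordinary least squares of `ln(sGFR)` on the design
#' `{1, min(ln(Scr/kappa_sex), 0), max(ln(Scr/kappa_sex), 0), age, [female],
#' covariates...}` over the records carrying the development label (plus
#' the internal-validation records when `pool_internal = TRUE`). Records
#' missing the outcome or a required covariate are a hard error — the
#' fitting never imputes.
#'
#' @param cohort a `cohort`; records with `split == "development"` are used
#'   (all records if none carry split labels, i.e. all `unassigned`).
#' @param vset a variable-set name (`"eq1"`..`"eq8"`, see
#'   [variable_sets()]) or a character vector of covariates among
#'   `bmi`, `hba1c`, `uacr`.
#' @param knots named creatinine knots `c(female = 0.7, male = 0.8)` mg/dL.
#' @param pool_internal also use internal-validation records for the fit.
#' @return list with components `model` (a [spline_model()]) and
#'   `diagnostics` (`n_used`, `residual_sd`, `r_squared`,
#'   `coefficient_se`).
#' @export
fit_spline_equation <- function(cohort, vset = "eq1",
                                knots = c(female = 0.7, male = 0.8),
                                pool_internal = FALSE) {
  covariates <- resolve_vset(vset)
  use <- if (all(cohort$split == "unassigned")) {
    rep(TRUE, nrow(cohort))
  } else {
    cohort$split == "development" | (pool_internal & cohort$split == "internal")
  }
  dat <- cohort[use, , drop = FALSE]
  if (nrow(dat) == 0) abort_gfrdm("no development records to fit", "gfrdm_insufficient_data_error")
  needed <- c("sgfr", covariates)
  for (col in needed) {
    n_miss <- sum(is.na(dat[[col]]))
    if (n_miss > 0) {
      abort_gfrdm(sprintf("field '%s' missing for %d development record(s); fits never impute", col, n_miss),
                  "gfrdm_missing_field_error")
    }
  }
  X <- spline_design(dat, covariates, knots)
  y <- log(dat$sgfr)
  p <- ncol(X) + 1L
  if (nrow(dat) < p + 1L) {
    abort_gfrdm(sprintf("need at least %d records to fit %d coefficients", p + 1L, p),
                "gfrdm_insufficient_data_error")
  }
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", colnames(X))
  if (anyNA(cf)) {
    abort_gfrdm(sprintf("collinear design; aliased column(s): %s",
                        paste(names(cf)[is.na(cf)], collapse = ", ")),
                "gfrdm_collinearity_error")
  }
  sm <- suppressWarnings(summary(fit))  # perfect fits (zero noise) are legitimate
  se <- stats::setNames(sm$coefficients[, "Std. Error"], names(cf))
  model <- spline_model(intercept = cf[["(Intercept)"]],
                        slope_below = cf[["scr_below"]],
                        slope_above = cf[["scr_above"]],
                        age_coef = cf[["age"]],
                        female_coef = cf[["female"]],
                        covariate_coefs = cf[covariates],
                        knot_female = knots[["female"]], knot_male = knots[["male"]])
  diagnostics <- list(n_used = nrow(dat), residual_sd = sm$sigma,
                      r_squared = sm$r.squared, coefficient_se = se)
  list(model = model, diagnostics = diagnostics)
}

#' Fit all eight equation variable sets
#'
#' Applies [fit_spline_equation()] to `eq1`..`eq8`. A variable set whose
#' covariates are entirely absent from the cohort (all `NA`) is skipped
#' with a warning; partially missing covariates remain a hard error.
#'
#' @inheritParams fit_spline_equation
#' @return named list of `fit_spline_equation` results for the fitted sets.
#' @export
fit_all_equations <- function(cohort, knots = c(female = 0.7, male = 0.8),
                              pool_internal = FALSE) {
  if (nrow(cohort) == 0) abort_gfrdm("empty cohort", "gfrdm_insufficient_data_error")
  out <- list()
  for (nm in names(variable_sets())) {
    covs <- variable_sets()[[nm]]
    absent <- covs[vapply(covs, function(cv) all(is.na(cohort[[cv]])), logical(1))]
    if (length(absent)) {
      warning(sprintf("skipping %s: covariate(s) %s absent from the cohort",
                      nm, paste(absent, collapse = ", ")), call. = FALSE)
      next
    }
    out[[nm]] <- fit_spline_equation(cohort, nm, knots = knots, pool_internal = pool_internal)
  }
  out
}

#' Nonparametric smoothing-spline shape diagnostic
#'
#' Fits a smoothing spline of `ln(sGFR)` on `ln(Scr)` separately per sex,
#' the diagnostic used to justify approximating the relationship by a
#' two-slope linear spline. Not part of the prediction path.
#'
#' @param cohort a `cohort` with `sgfr` present; needs >= 20 records per sex.
#' @param df equivalent degrees of freedom of the smooth (default 4).
#' @param grid_n number of grid points per sex curve.
#' @return named list (`F`, `M`) of data frames with columns `log_scr` and
#'   `log_sgfr_fit` evaluated on an even grid over the observed range.
#' @export
smoothing_spline_diagnostic <- function(cohort, df = 4, grid_n = 101) {
  dat <- cohort[!is.na(cohort$sgfr), , drop = FALSE]
  out <- list()
  for (sx in c("F", "M")) {
    d <- dat[dat$sex == sx, , drop = FALSE]
    if (nrow(d) < 20) {
      abort_gfrdm(sprintf("need >= 20 records with sgfr for sex %s, got %d", sx, nrow(d)),
                  "gfrdm_insufficient_data_error")
    }
    x <- log(d$scr); y <- log(d$sgfr)
    grid <- seq(min(x), max(x), length.out = grid_n)
    if (stats::sd(y) == 0) {
      out[[sx]] <- data.frame(log_scr = grid, log_sgfr_fit = rep(y[1], grid_n))
      next
    }
    ss <- stats::smooth.spline(x, y, df = df)
    out[[sx]] <- data.frame(log_scr = grid, log_sgfr_fit = stats::predict(ss, grid)$y)
  }
  out
}
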