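## Synthetic diabetic cohort generator. Marginals default to the
## development + internal validation cohort characteristics: age
## 59.8 +/- 13.1 y, BMI 25.0 +/- 3.5 kg/m^2, Scr median 0.8 (IQR 0.6)
## mg/dL, HbA1c median 8.5 (IQR 3.4) %, UACR median 42.6 (IQR 219.0) mg/g,
## 54.3 % male, with ground-truth GFR from a configurable model plus
## multiplicative log-normal noise.

#' Default ground-truth GFR model for simulation
#'
#' A two-slope log-spline model in the CKD-EPI lineage (steep decline in
#' eGFR above the sex knot, shallow below, mild age decline, small female
#' offset), chosen so that simulated standard GFR lands in a realistic
#' diabetic range (roughly 80 +/- 30 mL/min/1.73 m^2 at the default
#' covariate marginals).
#'
#' @return a [spline_model()].
#' @export
default_truth_model <- function() {
  spline_model(intercept = 4.90, slope_below = -0.35, slope_above = -1.10,
               age_coef = -0.007, female_coef = 0.02)
}

#' Simulation configuration for a synthetic diabetic cohort
#'
#' Distribution families: sex Bernoulli; age and BMI truncated normal
#' (age >= 18, BMI > 0); Scr, HbA1c and UACR log-normal, parameterized
#' from their natural-scale median and IQR via
#' [lnorm_from_median_iqr()] (right-skewed labs; the UACR IQR far exceeds
#' its median). Standard GFR is `truth(record) * exp(eps)` with
#' `eps ~ N(0, noise_sigma^2)`. Covariates are independent by default; an
#' optional Gaussian-copula correlation matrix over
#' (sex, age, bmi, scr, hba1c, uacr) induces joint structure without
#' changing the marginals.
#'
#' @param n cohort size (>= 1).
#' @param male_fraction proportion male in \[0, 1\].
#' @param age_mean,age_sd years.
#' @param bmi_mean,bmi_sd kg/m^2.
#' @param scr_median,scr_iqr mg/dL.
#' @param hba1c_median,hba1c_iqr percent.
#' @param uacr_median,uacr_iqr mg/g.
#' @param noise_sigma SD of the log-scale GFR noise.
#' @param truth generating GFR model (a `spline_model` or `ann_model`).
#' @param copula optional 6 x 6 correlation matrix (order: sex, age, bmi,
#'   scr, hba1c, uacr) for a Gaussian copula; `NULL` = independence.
#' @param seed integer seed.
#' @return object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n,
                              male_fraction = 0.543,
                              age_mean = 59.8, age_sd = 13.1,
                              bmi_mean = 25.0, bmi_sd = 3.5,
                              scr_median = 0.8, scr_iqr = 0.6,
                              hba1c_median = 8.5, hba1c_iqr = 3.4,
                              uacr_median = 42.6, uacr_iqr = 219.0,
                              noise_sigma = 0.25,
                              truth = default_truth_model(),
                              copula = NULL,
                              seed = NULL) {
  stopifnot(n >= 1, male_fraction >= 0, male_fraction <= 1,
            age_sd > 0, bmi_sd > 0, scr_median > 0, scr_iqr > 0,
            hba1c_median > 0, hba1c_iqr > 0, uacr_median > 0, uacr_iqr > 0,
            noise_sigma >= 0)
  if (!is.null(copula)) {
    stopifnot(is.matrix(copula), dim(copula) == c(6, 6), isSymmetric(copula),
              all(diag(copula) == 1))
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

#' Generate a synthetic diabetic cohort
#'
#' Draws covariates per the configured marginals, then assigns each record
#' a standard GFR from the ground-truth model times multiplicative
#' log-normal noise. Deterministic for a fixed seed. With
#' `noise_sigma = 0`, `sgfr` equals the truth model's prediction exactly.
#'
#' @param config a [cohort_sim_config()].
#' @return a `cohort` with all records labelled `unassigned`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n
  with_seed(config$seed, {
    z <- matrix(stats::rnorm(n * 6L), nrow = n, ncol = 6L)
    if (!is.null(config$copula)) {
      z <- z %*% chol(config$copula)
    }
    colnames(z) <- c("sex", "age", "bmi", "scr", "hba1c", "uacr")
    sex <- ifelse(stats::pnorm(z[, "sex"]) < config$male_fraction, "M", "F")
    age <- truncnorm_from_z(z[, "age"], config$age_mean, config$age_sd, lower = 18)
    bmi <- truncnorm_from_z(z[, "bmi"], config$bmi_mean, config$bmi_sd, lower = 0)
    pscr <- lnorm_from_median_iqr(config$scr_median, config$scr_iqr)
    phba <- lnorm_from_median_iqr(config$hba1c_median, config$hba1c_iqr)
    puacr <- lnorm_from_median_iqr(config$uacr_median, config$uacr_iqr)
    scr <- exp(pscr$meanlog + pscr$sdlog * z[, "scr"])
    hba1c <- exp(phba$meanlog + phba$sdlog * z[, "hba1c"])
    uacr <- exp(puacr$meanlog + puacr$sdlog * z[, "uacr"])
    df <- data.frame(id = sprintf("sim%05d", seq_len(n)), sex = sex, age = age,
                     scr = scr, bmi = bmi, hba1c = hba1c, uacr = uacr,
                     stringsAsFactors = FALSE)
    truth_gfr <- tryCatch(predict(config$truth, df),
                          gfrdm_evaluation_error = function(e) {
                            abort_gfrdm(paste0("truth model needs a field the generator did not produce: ",
                                               conditionMessage(e)),
                                        "gfrdm_config_error")
                          })
    eps <- if (config$noise_sigma > 0) stats::rnorm(n, 0, config$noise_sigma) else 0
    df$sgfr <- truth_gfr * exp(eps)
    as_cohort(df)
  })
}

## closed-on-left, open-on-right binning used throughout the summaries
bin_counts <- function(x, breaks, labels) {
  x <- x[!is.na(x)]
  cut_idx <- findInterval(x, breaks, left.open = FALSE)
  counts <- tabulate(cut_idx, nbins = length(labels))
  stats::setNames(counts, labels)
}

#' Summarize a cohort in the style of a clinical characteristics table
#'
#' Reports mean +/- SD for age, BMI and sGFR; median (IQR) for Scr, HbA1c
#' and UACR; and category percentages over the conventional clinical bins
#' (BMI <20 / 20-25 / 25-30 / >30 kg/m^2; HbA1c <6 / 6-8 / >8 %;
#' UACR <30 / 30-300 / >300 mg/g; sGFR <15 / 15-29 / 30-59 / 60-90 / >90
#' mL/min/1.73 m^2). Bins are closed on the left and open on the right.
#' The SD of a singleton sample is reported as 0. Quantiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param cohort a non-empty `cohort`.
#' @return a list with components `n`, `male_percent`, `continuous`
#'   (data frame of mean/sd/median/iqr per variable) and `bins` (named
#'   count vectors with percentage attributes).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) abort_gfrdm("empty cohort", "gfrdm_insufficient_data_error")
  sd0 <- function(x) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = TRUE)
  iqr7 <- function(x) diff(stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE))
  cont <- data.frame(
    variable = c("age", "bmi", "sgfr", "scr", "hba1c", "uacr"),
    mean = vapply(cohort[c("age", "bmi", "sgfr", "scr", "hba1c", "uacr")],
                  function(x) mean(x, na.rm = TRUE), numeric(1)),
    sd = vapply(cohort[c("age", "bmi", "sgfr", "scr", "hba1c", "uacr")], sd0, numeric(1)),
    median = vapply(cohort[c("age", "bmi", "sgfr", "scr", "hba1c", "uacr")],
                    function(x) stats::median(x, na.rm = TRUE), numeric(1)),
    iqr = vapply(cohort[c("age", "bmi", "sgfr", "scr", "hba1c", "uacr")], iqr7, numeric(1)),
    row.names = NULL)
  bins <- list(
    bmi = bin_counts(cohort$bmi, c(-Inf, 20, 25, 30), c("<20", "20-25", "25-30", ">=30")),
    hba1c = bin_counts(cohort$hba1c, c(-Inf, 6, 8), c("<6", "6-8", ">=8")),
    uacr = bin_counts(cohort$uacr, c(-Inf, 30, 300), c("<30", "30-300", ">=300")),
    sgfr = bin_counts(cohort$sgfr, c(-Inf, 15, 30, 60, 90), c("<15", "15-29", "30-59", "60-90", ">=90")))
  bins <- lapply(bins, function(b) {
    attr(b, "percent") <- if (sum(b) > 0) 100 * b / sum(b) else b * NA_real_
    b
  })
  list(n = nrow(cohort),
       male_percent = 100 * mean(cohort$sex == "M"),
       continuous = cont,
       bins = bins)
}
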