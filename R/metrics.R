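## Validation metrics: bias (median difference), precision (IQR of the
## differences), P30 accuracy (percent of estimates within 30 % of the
## reference), each with percentile bootstrap confidence intervals.

#' Paired reference / estimated GFR predictions
#'
#' Evaluates one or more models on every record of a cohort that carries a
#' reference `sgfr`, producing the paired table the validation metrics
#' operate on.
#'
#' @param cohort a `cohort` with `sgfr` present.
#' @param models named list; each element is a built-in equation name
#'   (`"ckd_epi"`, `"japanese_1"`, `"japanese_2"`) or a fitted
#'   `spline_model` / `ann_model`.
#' @return data frame of class `paired_predictions` with column `sgfr` and
#'   one eGFR column per model.
#' @export
paired_predictions <- function(cohort, models) {
  if (is.null(names(models)) || any(names(models) == "")) {
    abort_validation("models must be a fully named list")
  }
  if (anyNA(cohort$sgfr)) {
    abort_gfrdm("every record needs sgfr for paired evaluation", "gfrdm_missing_field_error")
  }
  out <- data.frame(sgfr = cohort$sgfr)
  for (nm in names(models)) {
    m <- models[[nm]]
    out[[nm]] <- if (is.character(m)) {
      switch(m,
             ckd_epi = ckd_epi(cohort$sex, cohort$age, cohort$scr),
             japanese_1 = japanese_1(cohort$sex, cohort$age, cohort$scr),
             japanese_2 = {
               if (anyNA(cohort$hba1c)) {
                 abort_gfrdm("japanese_2 requires hba1c on every record", "gfrdm_evaluation_error")
               }
               japanese_2(cohort$sex, cohort$age, cohort$scr, cohort$hba1c)
             },
             abort_validation(sprintf("unknown built-in equation '%s'", m)))
    } else {
      predict(m, cohort)
    }
  }
  class(out) <- c("paired_predictions", "data.frame")
  out
}

paired_diff <- function(paired, model, sign = c("egfr_minus_sgfr", "sgfr_minus_egfr")) {
  sign <- match.arg(sign)
  if (!model %in% names(paired)) {
    abort_gfrdm(sprintf("no predictions for model '%s'", model), "gfrdm_key_error")
  }
  d <- paired[[model]] - paired$sgfr
  if (sign == "sgfr_minus_egfr") -d else d
}

#' Bias: median of the paired eGFR - sGFR differences
#'
#' The sign convention defaults to eGFR - sGFR, so an equation that
#' underestimates GFR has negative bias; `sign = "sgfr_minus_egfr"` flips
#' it (the literature uses both).
#'
#' @param paired a [paired_predictions()] table.
#' @param model model column name.
#' @param sign difference direction.
#' @return median difference, mL/min/1.73 m^2.
#' @export
bias <- function(paired, model, sign = "egfr_minus_sgfr") {
  stats::median(paired_diff(paired, model, sign))
}

#' Precision: interquartile range of the paired differences
#'
#' Q3 - Q1 of the differences under linear-interpolation (type 7)
#' quantiles; invariant to the bias sign convention.
#'
#' @inheritParams bias
#' @return IQR, mL/min/1.73 m^2.
#' @export
precision_iqr <- function(paired, model, sign = "egfr_minus_sgfr") {
  d <- paired_diff(paired, model, sign)
  if (length(d) < 2) abort_gfrdm("precision needs at least 2 records", "gfrdm_insufficient_data_error")
  diff(stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE))
}

#' P30 accuracy: percent of estimates within 30 % of the reference
#'
#' `100 * #( |eGFR - sGFR| / sGFR <= 0.30 ) / n`; the 30 % boundary counts
#' as within.
#'
#' @inheritParams bias
#' @return percent in \[0, 100\].
#' @export
p30_accuracy <- function(paired, model, sign = "egfr_minus_sgfr") {
  if (!model %in% names(paired)) {
    abort_gfrdm(sprintf("no predictions for model '%s'", model), "gfrdm_key_error")
  }
  if (any(paired$sgfr <= 0)) abort_gfrdm("sgfr must be positive for P30", "gfrdm_domain_error")
  ok <- abs(paired[[model]] - paired$sgfr) / paired$sgfr <= 0.30
  100 * sum(ok) / length(ok)
}

#' Percentile bootstrap confidence interval for a validation metric
#'
#' Resamples records with replacement `reps` times, recomputes the metric
#' on each resample, and returns the 2.5th and 97.5th percentiles (for the
#' default 95 % level). Deterministic for a fixed seed; `seed = NULL`
#' draws from the current RNG stream.
#'
#' @param metric one of `"bias"`, `"precision_iqr"`, `"p30_accuracy"`, or
#'   a `function(paired, model)`.
#' @inheritParams bias
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(metric, paired, model, reps = 2000, seed = NULL,
                         conf = 0.95, sign = "egfr_minus_sgfr") {
  stopifnot(reps >= 1)
  n <- nrow(paired)
  # For the built-in metrics a record resample is fully determined by the
  # record's error, so resample precomputed per-record vectors instead of
  # subsetting the data frame; results are numerically identical.
  call_idx <- if (is.character(metric)) {
    metric <- match.arg(metric, c("bias", "precision_iqr", "p30_accuracy"))
    switch(metric,
      bias = {
        d <- paired_diff(paired, model, sign)
        function(idx) stats::median(d[idx])
      },
      precision_iqr = {
        d <- paired_diff(paired, model, sign)
        if (n < 2) abort_gfrdm("precision needs at least 2 records", "gfrdm_insufficient_data_error")
        function(idx) diff(stats::quantile(d[idx], c(0.25, 0.75), type = 7, names = FALSE))
      },
      p30_accuracy = {
        if (any(paired$sgfr <= 0)) abort_gfrdm("sgfr must be positive for P30", "gfrdm_domain_error")
        ok <- abs(paired[[model]] - paired$sgfr) / paired$sgfr <= 0.30
        function(idx) 100 * sum(ok[idx]) / n
      })
  } else {
    function(idx) metric(paired[idx, , drop = FALSE], model)
  }
  stats_boot <- with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      call_idx(sample.int(n, n, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7, names = FALSE)
}
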