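## Assembled validation report: one row per model with bias / precision /
## P30 and bootstrap CIs, plus Wilcoxon and McNemar p-values against a
## designated reference model.

#' Validation report with reference-model comparisons
#'
#' Computes, for every model column of a paired-prediction table, the
#' three validation metrics with percentile bootstrap 95 % confidence
#' intervals, and compares each model against the reference: Wilcoxon
#' signed-rank on absolute errors and McNemar on the within-30 %
#' indicators. The reference compared to itself is degenerate and reports
#' p = 1.
#'
#' @param paired a [paired_predictions()] table.
#' @param models model columns to report (default: all, in table order).
#' @param reference model name the comparisons are made against.
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed for all bootstrap resampling.
#' @param sign bias sign convention, see [bias()].
#' @return data frame of class `table3_report`: one row per model with
#'   `n`, `bias`, `bias_lo`, `bias_hi`, `precision`, `precision_lo`,
#'   `precision_hi`, `p30`, `p30_lo`, `p30_hi`, `p_wilcoxon`, `p_mcnemar`.
#' @export
table3_report <- function(paired, models = NULL, reference = "ckd_epi",
                          reps = 2000, seed = NULL, sign = "egfr_minus_sgfr") {
  if (is.null(models)) models <- setdiff(names(paired), "sgfr")
  if (!reference %in% names(paired)) {
    abort_gfrdm(sprintf("reference model '%s' not in the paired table", reference), "gfrdm_key_error")
  }
  with_seed(seed, {
    rows <- lapply(models, function(nm) {
      b_ci <- bootstrap_ci("bias", paired, nm, reps = reps, sign = sign)
      p_ci <- bootstrap_ci("precision_iqr", paired, nm, reps = reps, sign = sign)
      a_ci <- bootstrap_ci("p30_accuracy", paired, nm, reps = reps, sign = sign)
      data.frame(model = nm, n = nrow(paired),
                 bias = bias(paired, nm, sign = sign),
                 bias_lo = b_ci[1], bias_hi = b_ci[2],
                 precision = precision_iqr(paired, nm),
                 precision_lo = p_ci[1], precision_hi = p_ci[2],
                 p30 = p30_accuracy(paired, nm),
                 p30_lo = a_ci[1], p30_hi = a_ci[2],
                 p_wilcoxon = compare_bias_wilcoxon(paired, nm, reference)$p_value,
                 p_mcnemar = compare_accuracy_mcnemar(paired, nm, reference)$p_value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "reference") <- reference
    class(out) <- c("table3_report", "data.frame")
    out
  })
}

#' @export
print.table3_report <- function(x, digits = 2, ...) {
  cat(sprintf("Validation report (n = %d, reference = %s)\n", x$n[1], attr(x, "reference")))
  d <- data.frame(
    model = x$model,
    `bias [95% CI]` = sprintf("%.*f [%.*f, %.*f]", digits, x$bias, digits, x$bias_lo, digits, x$bias_hi),
    `precision [95% CI]` = sprintf("%.*f [%.*f, %.*f]", digits, x$precision, digits, x$precision_lo, digits, x$precision_hi),
    `P30 % [95% CI]` = sprintf("%.1f [%.1f, %.1f]", x$p30, x$p30_lo, x$p30_hi),
    p_wilcoxon = signif(x$p_wilcoxon, 3),
    p_mcnemar = signif(x$p_mcnemar, 3),
    check.names = FALSE)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Write a validation report as delimited text
#'
#' @param report a [table3_report()].
#' @param path output path.
#' @param sep separator (default tab).
#' @export
write_report <- function(report, path, sep = "\t") {
  utils::write.table(as.data.frame(report), path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
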