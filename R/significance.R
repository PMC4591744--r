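## Paired significance tests between models (Wilcoxon signed-rank on
## absolute errors; McNemar on within-30 % indicators) and two-cohort
## comparisons (t test / Mann-Whitney), all two-sided.

gfr_test <- function(statistic, p_value, method, exact, degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 exact = exact, degenerate = degenerate),
            class = "gfr_test")
}

#' @export
print.gfr_test <- function(x, ...) {
  cat(sprintf("%s\nstatistic = %g, p = %.5g (%s%s)\n", x$method, x$statistic,
              x$p_value, if (x$exact) "exact" else "asymptotic",
              if (x$degenerate) ", degenerate data" else ""))
  invisible(x)
}

## two-sided Wilcoxon signed-rank p-value for paired differences d.
## Zeros dropped; exact null (via the signed-rank distribution) when
## n <= exact_max and |d| are tie-free, else normal approximation with
## continuity and tie corrections.
wilcoxon_signed_rank <- function(d, exact_max = 25) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(gfr_test(NA_real_, 1, "Wilcoxon signed-rank test", exact = TRUE, degenerate = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= exact_max && !ties) {
    p <- 2 * min(stats::psignrank(V, n), 1 - stats::psignrank(V - 1, n))
    return(gfr_test(V, min(p, 1), "Wilcoxon signed-rank test", exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
  gfr_test(V, min(1, 2 * stats::pnorm(-abs(z))), "Wilcoxon signed-rank test", exact = FALSE)
}

#' Compare two models' errors by the Wilcoxon signed-rank test
#'
#' Paired two-sided test on the per-record absolute errors
#' `|eGFR_A - sGFR|` vs `|eGFR_B - sGFR|` (the standard reading of an
#' accuracy comparison between estimating equations). Zero pairs are
#' dropped per the Wilcoxon convention; if every pair is zero (e.g., the
#' models coincide) the test is degenerate and p = 1 is returned with the
#' `degenerate` flag set. The exact signed-rank null is used for n <= 25
#' without ties, the continuity-corrected normal approximation otherwise.
#'
#' @param paired a [paired_predictions()] table.
#' @param model_a,model_b model column names.
#' @return a `gfr_test` (fields `statistic`, `p_value`, `method`, `exact`,
#'   `degenerate`).
#' @export
compare_bias_wilcoxon <- function(paired, model_a, model_b) {
  da <- abs(paired_diff(paired, model_a))
  db <- abs(paired_diff(paired, model_b))
  wilcoxon_signed_rank(da - db)
}

#' Compare two models' P30 accuracy by the McNemar test
#'
#' Builds the per-record within-30 % indicators for both models and tests
#' the discordant counts (`b` = within for A only, `c` = within for B
#' only). Exact two-sided binomial test when `b + c <= 25`, chi-square
#' with continuity correction otherwise; `b = c = 0` is degenerate
#' (p = 1).
#'
#' @inheritParams compare_bias_wilcoxon
#' @return a `gfr_test`; `statistic` is `b - c`.
#' @export
compare_accuracy_mcnemar <- function(paired, model_a, model_b) {
  within <- function(model) {
    abs(paired[[model]] - paired$sgfr) / paired$sgfr <= 0.30
  }
  for (m in c(model_a, model_b)) {
    if (!m %in% names(paired)) abort_gfrdm(sprintf("no predictions for model '%s'", m), "gfrdm_key_error")
  }
  wa <- within(model_a); wb <- within(model_b)
  b <- sum(wa & !wb); cc <- sum(!wa & wb)
  if (b + cc == 0) {
    return(gfr_test(0, 1, "McNemar test", exact = TRUE, degenerate = TRUE))
  }
  if (b + cc <= 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    gfr_test(b - cc, p, "McNemar test", exact = TRUE)
  } else {
    x2 <- (abs(b - cc) - 1)^2 / (b + cc)
    gfr_test(b - cc, stats::pchisq(x2, 1, lower.tail = FALSE), "McNemar test", exact = FALSE)
  }
}

## exact two-sided Mann-Whitney by enumeration of all group assignments
## (handles ties via average ranks; feasible for small total n)
mann_whitney_exact <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  mu <- nx * (N + 1) / 2
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  combos <- utils::combn(N, nx)
  w <- abs(colSums(matrix(r[combos], nrow = nx)) - mu)
  mean(w >= obs - 1e-9)
}

#' Compare a variable between two cohorts
#'
#' Two-sample comparison in the reporting style of a clinical
#' characteristics table: Welch t test for the approximately normal
#' variables (age, BMI, sGFR), Mann-Whitney for the skewed labs (Scr,
#' HbA1c, UACR). The Mann-Whitney p-value is exact by enumeration of all
#' group assignments when the pooled size is <= `exact_max_total`
#' (ties handled by average ranks), and the continuity-corrected normal
#' approximation otherwise.
#'
#' @param cohort_a,cohort_b `cohort`s.
#' @param variable column name present in both cohorts.
#' @param exact_max_total pooled-size cutoff for the exact Mann-Whitney.
#' @return two-sided p-value.
#' @export
compare_cohorts <- function(cohort_a, cohort_b, variable, exact_max_total = 10) {
  x <- cohort_a[[variable]]; y <- cohort_b[[variable]]
  if (is.null(x) || is.null(y)) {
    abort_gfrdm(sprintf("variable '%s' not present in both cohorts", variable), "gfrdm_key_error")
  }
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) abort_gfrdm("empty group", "gfrdm_insufficient_data_error")
  normal_vars <- c("age", "bmi", "sgfr", "weight", "height")
  if (variable %in% normal_vars) {
    stats::t.test(x, y)$p.value
  } else if (length(x) + length(y) <= exact_max_total) {
    mann_whitney_exact(x, y)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}
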