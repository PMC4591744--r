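#' @keywords internal
"_PACKAGE"

sigmoid <- function(z) 1 / (1 + exp(-z))

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched. seed = NULL runs on the current stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

abort_gfrdm <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gfrdm_error")))
}

abort_validation <- function(msg) abort_gfrdm(msg, "gfrdm_validation_error")
abort_format <- function(msg) abort_gfrdm(msg, "gfrdm_format_error")

#' Log-normal parameters from a median and interquartile range
#'
#' Converts the median / IQR summaries reported for right-skewed labs
#' (serum creatinine, HbA1c, UACR) into the `meanlog` / `sdlog`
#' parameterization of a log-normal, by matching the 25th and 75th
#' percentiles: for a log-normal the natural-scale IQR equals
#' `2 * median * sinh(z * sdlog)` with `z = qnorm(0.75)`.
#'
#' @param median natural-scale median (> 0).
#' @param iqr natural-scale interquartile range (> 0).
#' @return list with components `meanlog` and `sdlog`.
#' @examples
#' p <- lnorm_from_median_iqr(0.8, 0.6)
#' qlnorm(0.5, p$meanlog, p$sdlog)  # 0.8
#' @export
lnorm_from_median_iqr <- function(median, iqr) {
  stopifnot(median > 0, iqr > 0)
  z <- stats::qnorm(0.75)
  list(meanlog = log(median), sdlog = asinh(iqr / (2 * median)) / z)
}

## inverse-CDF truncated-normal transform of standard-normal draws
truncnorm_from_z <- function(z, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::pnorm(z) * (phi - plo), mean, sd)
}

fmt_num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
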