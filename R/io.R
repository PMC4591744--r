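## Flat key/value text serialization for fitted models: one "key<TAB>value"
## line per scalar, full double precision, a "type" line first. Vector and
## matrix entries use dotted index suffixes (w_in.2.3 = hidden 2, input 3).

write_kv <- function(kv, path) {
  lines <- vapply(names(kv), function(k) {
    v <- kv[[k]]
    paste0(k, "\t", if (is.character(v)) v else fmt_num(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_kv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[2]), vapply(parts, `[[`, character(1), 1))
}

#' Write a fitted model to a flat text file
#'
#' Serializes a `spline_model`, `ann_model` or `calibration_model` as
#' tab-separated key/value lines with full double precision, so a
#' write/read round trip reproduces the model exactly.
#'
#' @param model the model object.
#' @param path output path.
#' @export
write_model <- function(model, path) UseMethod("write_model")

#' @export
write_model.spline_model <- function(model, path) {
  kv <- list(type = "spline",
             knot_female = model$knot_female, knot_male = model$knot_male,
             intercept = model$intercept, slope_below = model$slope_below,
             slope_above = model$slope_above, age_coef = model$age_coef,
             female_coef = model$female_coef)
  for (cov in names(model$covariate_coefs)) {
    kv[[paste0("coef.", cov)]] <- model$covariate_coefs[[cov]]
  }
  write_kv(kv, path)
}

#' @export
write_model.calibration_model <- function(model, path) {
  write_kv(list(type = "calibration", intercept = model$intercept,
                slope = model$slope, r_squared = model$r_squared,
                n = model$n), path)
}

#' @export
write_model.ann_model <- function(model, path) {
  kv <- list(type = "ann",
             inputs = paste(model$inputs, collapse = ","),
             n_hidden = model$n_hidden,
             t_out = model$b2,
             output_lo = model$output_lo, output_hi = model$output_hi)
  for (i in seq_along(model$inputs)) {
    kv[[paste0("input_lo.", model$inputs[i])]] <- model$input_lo[[i]]
    kv[[paste0("input_hi.", model$inputs[i])]] <- model$input_hi[[i]]
  }
  for (j in seq_len(model$n_hidden)) {
    for (i in seq_along(model$inputs)) {
      kv[[sprintf("w_in.%d.%d", j, i)]] <- model$W1[j, i]
    }
    kv[[sprintf("t_hidden.%d", j)]] <- model$b1[j]
    kv[[sprintf("w_out.%d", j)]] <- model$w2[j]
  }
  write_kv(kv, path)
}

#' Read a model written by [write_model()]
#'
#' @param path model file path.
#' @return a `spline_model`, `ann_model` or `calibration_model`.
#' @export
read_model <- function(path) {
  kv <- read_kv(path)
  type <- kv$type
  if (is.null(type)) abort_format("model file has no 'type' line")
  num <- function(k) as.numeric(kv[[k]])
  switch(type,
    spline = {
      covs <- sub("^coef\\.", "", grep("^coef\\.", names(kv), value = TRUE))
      spline_model(intercept = num("intercept"),
                   slope_below = num("slope_below"), slope_above = num("slope_above"),
                   age_coef = num("age_coef"), female_coef = num("female_coef"),
                   covariate_coefs = stats::setNames(vapply(covs, function(cv) num(paste0("coef.", cv)), numeric(1)), covs),
                   knot_female = num("knot_female"), knot_male = num("knot_male"))
    },
    calibration = calibration_model(num("intercept"), num("slope"),
                                    num("r_squared"), as.integer(num("n"))),
    ann = {
      inputs <- strsplit(kv$inputs, ",", fixed = TRUE)[[1]]
      h <- as.integer(num("n_hidden"))
      p <- length(inputs)
      W1 <- matrix(NA_real_, h, p)
      for (j in seq_len(h)) for (i in seq_len(p)) W1[j, i] <- num(sprintf("w_in.%d.%d", j, i))
      ann_model(inputs, h, W1,
                b1 = vapply(seq_len(h), function(j) num(sprintf("t_hidden.%d", j)), numeric(1)),
                w2 = vapply(seq_len(h), function(j) num(sprintf("w_out.%d", j)), numeric(1)),
                b2 = num("t_out"),
                input_lo = vapply(inputs, function(f) num(paste0("input_lo.", f)), numeric(1)),
                input_hi = vapply(inputs, function(f) num(paste0("input_hi.", f)), numeric(1)),
                output_lo = num("output_lo"), output_hi = num("output_hi"))
    },
    abort_format(sprintf("unknown model type '%s'", type)))
}
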