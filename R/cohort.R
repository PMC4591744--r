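## Cohort container: a data.frame with one row per patient and columns
##   id      opaque label (character, unique)
##   sex     "F" or "M"
##   age     years (>= 18)
##   scr     serum creatinine, mg/dL (> 0)
##   bmi     kg/m^2        (optional, NA when absent)
##   hba1c   percent       (optional)
##   uacr    mg/g          (optional)
##   sgfr    standard GFR, mL/min/1.73 m^2 (optional)
##   split   "unassigned" / "development" / "internal" / "external"

COHORT_COLS <- c("id", "sex", "age", "scr", "bmi", "hba1c", "uacr", "sgfr", "split")
SPLIT_LEVELS <- c("unassigned", "development", "internal", "external")

#' Construct a cohort from a data frame
#'
#' Coerces a data frame of patient records into a validated `cohort` object.
#' Mandatory columns are `sex` (coded F/M, case-insensitive), `age` (years)
#' and `scr` (serum creatinine, mg/dL). Optional columns `bmi`, `hba1c`,
#' `uacr`, `sgfr` are kept as `NA` where absent; they are never imputed.
#'
#' @param df data frame with at least `sex`, `age`, `scr`.
#' @return object of class `cohort` (a data.frame).
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("sex", "age", "scr")) {
    if (!col %in% names(df)) {
      abort_format(sprintf("mandatory column '%s' is missing", col))
    }
  }
  n <- nrow(df)
  if (!"id" %in% names(df)) df$id <- sprintf("p%04d", seq_len(n))
  df$id <- as.character(df$id)
  df$sex <- toupper(as.character(df$sex))
  for (col in c("bmi", "hba1c", "uacr", "sgfr")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    df[[col]] <- as.numeric(df[[col]])
  }
  df$age <- as.numeric(df$age)
  df$scr <- as.numeric(df$scr)
  if (!"split" %in% names(df)) df$split <- "unassigned"
  df$split <- as.character(df$split)
  df <- df[COHORT_COLS]
  rownames(df) <- NULL
  validate_cohort(df)
  structure(df, class = c("cohort", "data.frame"))
}

validate_cohort <- function(df) {
  fail <- function(id, msg) {
    abort_validation(sprintf("record '%s': %s", id, msg))
  }
  if (anyDuplicated(df$id)) {
    abort_validation(sprintf("duplicated record ids: %s",
                             paste(unique(df$id[duplicated(df$id)]), collapse = ", ")))
  }
  bad_split <- setdiff(unique(df$split), SPLIT_LEVELS)
  if (length(bad_split)) {
    abort_validation(sprintf("unknown split label(s): %s", paste(bad_split, collapse = ", ")))
  }
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$sex) || !r$sex %in% c("F", "M")) {
      fail(r$id, sprintf("sex must be F or M, got '%s'", r$sex))
    }
    if (is.na(r$age) || r$age < 18) {
      fail(r$id, sprintf("age %s is below the adult inclusion threshold of 18 years", r$age))
    }
    if (is.na(r$scr) || r$scr <= 0) fail(r$id, "scr must be > 0 mg/dL")
    if (!is.na(r$sgfr) && r$sgfr <= 0) fail(r$id, "sgfr must be > 0 when present")
    if (!is.na(r$bmi) && r$bmi <= 0) fail(r$id, "bmi must be > 0 when present")
    if (!is.na(r$hba1c) && r$hba1c <= 0) fail(r$id, "hba1c must be > 0 when present")
    if (!is.na(r$uacr) && r$uacr < 0) fail(r$id, "uacr must be >= 0 when present")
  }
  invisible(df)
}

#' Read a patient cohort from delimited text
#'
#' Reads a comma- or tab-delimited file with a header row. Canonical column
#' names are `sex`, `age`, `scr_mg_dl`, `bmi`, `hba1c`, `uacr_mg_g`, `sgfr`
#' (plus optional `id` and `split`); `scr` and `uacr` are accepted as
#' aliases. Creatinine reported in µmol/L is converted to mg/dL by dividing
#' by 88.4 (the standard clinical factor).
#'
#' @param path file path.
#' @param scr_unit unit of the creatinine column: `"mg/dL"` (default) or
#'   `"umol/L"`.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from the
#'   header line.
#' @return a [as_cohort()] object.
#' @export
read_cohort <- function(path, scr_unit = c("mg/dL", "umol/L"), sep = NULL) {
  scr_unit <- match.arg(gsub("µ", "u", scr_unit[1]), c("mg/dL", "umol/L"))
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  # read everything as character: an all-"F" sex column must not become logical
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, colClasses = "character")
  nm <- names(df)
  nm[nm == "scr_mg_dl"] <- "scr"
  nm[nm == "uacr_mg_g"] <- "uacr"
  names(df) <- nm
  if (!"scr" %in% names(df)) {
    abort_format("mandatory column 'scr_mg_dl' is missing")
  }
  df$scr <- as.numeric(df$scr)
  if (scr_unit == "umol/L") df$scr <- df$scr / 88.4
  as_cohort(df)
}

#' Write a cohort to delimited text
#'
#' Inverse of [read_cohort()]: writes the canonical columns (`id`, `sex`,
#' `age`, `scr_mg_dl`, `bmi`, `hba1c`, `uacr_mg_g`, `sgfr`, `split`) with
#' full double precision so a write/read round trip reproduces every field.
#'
#' @param cohort a `cohort`.
#' @param path output path.
#' @param sep field separator (default comma).
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  out <- as.data.frame(cohort)
  names(out)[names(out) == "scr"] <- "scr_mg_dl"
  names(out)[names(out) == "uacr"] <- "uacr_mg_g"
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), NA, fmt_num(x)))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Randomly split a cohort into development and internal-validation sets
#'
#' Reassigns every record currently labelled `unassigned`, `development` or
#' `internal` by uniform random sampling without replacement; records
#' labelled `external` are never touched. The development set receives
#' `round(n * dev_fraction)` records (clamped so both sets are non-empty),
#' the remainder go to the internal set. With 414 eligible records and
#' `dev_fraction = 2/3` this yields the 276 / 138 development / internal
#' split used for model development and selection.
#'
#' @param cohort a `cohort`.
#' @param dev_fraction proportion assigned to development, in (0, 1).
#' @param seed integer seed; the assignment is deterministic for a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @return the cohort with updated `split` labels (record order preserved).
#' @export
split_cohort <- function(cohort, dev_fraction = 2 / 3, seed) {
  stopifnot(dev_fraction > 0, dev_fraction < 1)
  eligible <- which(cohort$split %in% c("unassigned", "development", "internal"))
  n <- length(eligible)
  if (n < 2) {
    abort_gfrdm("fewer than 2 records available for splitting", "gfrdm_insufficient_data_error")
  }
  n_dev <- round(n * dev_fraction)
  n_dev <- min(max(n_dev, 1L), n - 1L)
  dev_idx <- with_seed(seed, sample(eligible, n_dev))
  cohort$split[eligible] <- "internal"
  cohort$split[dev_idx] <- "development"
  cohort
}

#' Subset a cohort by split label
#'
#' @param cohort a `cohort`.
#' @param split one of `"development"`, `"internal"`, `"external"`,
#'   `"unassigned"`.
#' @return the matching records, still a `cohort`.
#' @export
cohort_subset <- function(cohort, split) {
  split <- match.arg(split, SPLIT_LEVELS)
  out <- cohort[cohort$split == split, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cohort <- function(x, ...) {
  counts <- table(factor(x$split, levels = SPLIT_LEVELS))
  cat(sprintf("<cohort> %d records (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(counts), counts), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
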