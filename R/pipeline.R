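## End-to-end orchestration: simulate -> split -> fit equations -> fit
## ANNs -> evaluate on an external set, writing every artifact as plain
## text with a timestamped log.

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full development / validation pipeline on synthetic cohorts
#'
#' Mirrors the study workflow: simulate a development + internal cohort
#' and a separate external cohort from the same generating truth, split
#' the former 2:1 into development and internal-validation sets, fit the
#' eight spline regression equations on the development records, train the
#' eight GABP networks (GA-initialized back-propagation with hidden-size
#' selection by internal-validation MSE), then evaluate everything —
#' together with the CKD-EPI and both Japanese comparator equations — on
#' the external set with bootstrap CIs and reference-model comparisons.
#'
#' Every artifact (cohort, model files, report) is written under
#' `out_dir` as delimited or flat key/value text; reruns with an identical
#' configuration reproduce them byte-identically.
#'
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed integer seed governing every stochastic stage (mandatory).
#' @param n_devint simulated development + internal cohort size.
#' @param n_external simulated external cohort size.
#' @param dev_fraction development share of the 2:1 split.
#' @param sim_config a [cohort_sim_config()] template; its `n` and `seed`
#'   are overridden per stage.
#' @param ann_sizes hidden sizes searched per ANN model.
#' @param train_cfg,ga_cfg ANN training / GA configurations. The pipeline
#'   defaults are scaled for interactive use (300 BP epochs, GA population
#'   12 over 6 generations, 20 inner epochs); pass larger configurations
#'   for a full search.
#' @param reps bootstrap replicates for the report.
#' @param reference reference model for the comparisons.
#' @return list with `cohort`, `external`, `equations`, `anns`, `paired`,
#'   `report`, and `paths` of the written artifacts.
#' @export
run_pipeline <- function(out_dir = NULL, seed,
                         n_devint = 414, n_external = 105,
                         dev_fraction = 2 / 3,
                         sim_config = cohort_sim_config(n = n_devint),
                         ann_sizes = c(4, 6, 8),
                         train_cfg = train_config(max_epochs = 300, patience = 100),
                         ga_cfg = ga_config(population_size = 12, generations = 6,
                                            inner_training_epochs = 20),
                         reps = 2000, reference = "ckd_epi") {
  if (missing(seed) || is.null(seed)) {
    abort_gfrdm("run_pipeline requires an explicit integer seed", "gfrdm_config_error")
  }
  paths <- list()
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$log <- file.path(out_dir, "pipeline.log")
    con <- file(paths$log, "w")
    on.exit(close(con), add = TRUE)
  }

  # stage: simulate
  sim_dev <- sim_config; sim_dev$n <- n_devint; sim_dev$seed <- seed
  sim_ext <- sim_config; sim_ext$n <- n_external; sim_ext$seed <- seed + 1L
  cohort <- generate_cohort(sim_dev)
  external <- generate_cohort(sim_ext)
  external$split <- "external"
  log_line(con, "simulate: n_devint=%d n_external=%d seed=%d", n_devint, n_external, seed)

  # stage: split 2:1 into development / internal
  cohort <- split_cohort(cohort, dev_fraction = dev_fraction, seed = seed + 2L)
  dev <- cohort_subset(cohort, "development")
  int <- cohort_subset(cohort, "internal")
  log_line(con, "split: development=%d internal=%d external=%d",
           nrow(dev), nrow(int), nrow(external))
  if (!is.null(out_dir)) {
    paths$cohort <- file.path(out_dir, "cohort_devint.csv")
    paths$external_cohort <- file.path(out_dir, "cohort_external.csv")
    write_cohort(cohort, paths$cohort)
    write_cohort(external, paths$external_cohort)
    paths$truth <- file.path(out_dir, "truth_model.txt")
    write_model(sim_config$truth, paths$truth)
  }

  # stage: fit the eight regression equations on the development records
  equations <- fit_all_equations(cohort)
  log_line(con, "fit-equation: %d models (%s)", length(equations),
           paste(names(equations), collapse = ", "))

  # stage: train the eight GABP networks
  anns <- list()
  for (nm in names(variable_sets())) {
    ann_nm <- sub("^eq", "ann", nm)
    tc <- train_cfg; tc$seed <- seed + 10L
    gc <- ga_cfg; gc$seed <- seed + 20L
    anns[[ann_nm]] <- train_gabp(dev, int, ann_nm, sizes = ann_sizes,
                                 cfg = tc, ga_cfg = gc)
    log_line(con, "fit-ann: %s topology %d-%d-1 internal_mse=%.5g", ann_nm,
             length(anns[[ann_nm]]$inputs), anns[[ann_nm]]$n_hidden,
             attr(anns[[ann_nm]], "trace")$best_internal_mse)
  }
  if (!is.null(out_dir)) {
    for (nm in names(equations)) {
      p <- file.path(out_dir, paste0("model_", nm, ".txt"))
      write_model(equations[[nm]]$model, p)
      paths[[paste0("model_", nm)]] <- p
    }
    for (nm in names(anns)) {
      p <- file.path(out_dir, paste0("model_", nm, ".txt"))
      write_model(anns[[nm]], p)
      paths[[paste0("model_", nm)]] <- p
    }
  }

  # stage: external validation report
  models <- c(list(ckd_epi = "ckd_epi", japanese_1 = "japanese_1",
                   japanese_2 = "japanese_2"),
              lapply(equations, `[[`, "model"),
              anns)
  paired <- paired_predictions(external, models)
  report <- table3_report(paired, reference = reference, reps = reps,
                          seed = seed + 30L)
  log_line(con, "evaluate: %d models on n=%d external records, %d bootstrap reps",
           length(models), nrow(external), reps)
  if (!is.null(out_dir)) {
    paths$report <- file.path(out_dir, "report.tsv")
    write_report(report, paths$report)
  }

  list(cohort = cohort, external = external, equations = equations,
       anns = anns, paired = paired, report = report, paths = paths)
}
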