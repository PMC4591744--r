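## Genetic-algorithm optimization of initial weights and thresholds
## (the GABP network). A chromosome is the real-valued concatenation of
## all weights and thresholds of one network; fitness is the
## internal-validation MSE reached after a short burst of back-propagation
## from that chromosome (inner_training_epochs = 0 scores the untrained
## chromosome). Selection keeps chromosomes that perform better in the
## internal validation set; the population evolves by crossover and
## Gaussian mutation under elitist generational replacement, and the best
## chromosome ever seen is returned.

#' Genetic-algorithm configuration
#'
#' @param population_size chromosomes per generation (>= 2).
#' @param generations number of generations (0 = score the random initial
#'   population only).
#' @param crossover_rate probability a child is produced by arithmetic
#'   (blend) crossover rather than cloning a parent, in \[0, 1\].
#' @param mutation_rate per-gene probability of Gaussian mutation, in
#'   \[0, 1\].
#' @param mutation_scale SD of the Gaussian mutation step.
#' @param inner_training_epochs BP epochs run inside each fitness
#'   evaluation (0 scores untrained chromosomes).
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, generations = 50,
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_scale = 0.1, inner_training_epochs = 50,
                      seed = NULL) {
  if (population_size < 2) {
    abort_gfrdm("population_size must be at least 2", "gfrdm_config_error")
  }
  stopifnot(generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            mutation_scale >= 0, inner_training_epochs >= 0)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 inner_training_epochs = as.integer(inner_training_epochs),
                 seed = seed), class = "ga_config")
}

#' Optimize a network's initial weights and thresholds by genetic algorithm
#'
#' @param inputs ANN inputs or variable-set name (see [ann_model()]).
#' @param n_hidden hidden-layer size of the target topology.
#' @param development,internal `cohort`s with `sgfr` and the inputs.
#' @param ga_cfg a [ga_config()].
#' @param train_cfg a [train_config()] whose learning rate / momentum are
#'   used for the inner fitness training bursts.
#' @return list with `chromosome` (best-ever initial weight vector),
#'   `model` (the corresponding untrained `ann_model`), `fitness` (its
#'   internal MSE after the inner training burst) and `best_history`
#'   (best-ever fitness after each generation, non-increasing).
#' @export
ga_optimize_init <- function(inputs, n_hidden, development, internal,
                             ga_cfg = ga_config(), train_cfg = train_config()) {
  stopifnot(inherits(ga_cfg, "ga_config"))
  inputs <- resolve_ann_inputs(inputs)
  X <- ann_feature_matrix(development, inputs)
  y <- development$sgfr
  if (anyNA(y)) abort_gfrdm("development records must carry sgfr", "gfrdm_missing_field_error")
  scal <- list(ilo = apply(X, 2, min), ihi = apply(X, 2, max),
               olo = min(y), ohi = max(y))
  L <- chromosome_length(length(inputs), n_hidden)
  inner_cfg <- train_config(learning_rate = train_cfg$learning_rate,
                            momentum = train_cfg$momentum,
                            max_epochs = max(ga_cfg$inner_training_epochs, 1L),
                            patience = Inf)
  decode <- function(theta) {
    ann_from_chromosome(theta, inputs, n_hidden, scal$ilo, scal$ihi, scal$olo, scal$ohi)
  }
  fitness <- function(theta) {
    m <- decode(theta)
    if (ga_cfg$inner_training_epochs > 0) {
      m <- train_bp(m, development, internal, inner_cfg)
      attr(m, "trace")$best_internal_mse
    } else {
      Xi <- minmax_scale(ann_feature_matrix(internal, inputs), scal$ilo, scal$ihi)
      yi <- (internal$sgfr - scal$olo) / (scal$ohi - scal$olo)
      mean((ann_forward_scaled(m, Xi)$yhat - yi)^2)
    }
  }
  with_seed(ga_cfg$seed, {
    np <- ga_cfg$population_size
    pop <- matrix(stats::runif(np * L, -0.5, 0.5), nrow = np)
    fit <- apply(pop, 1, fitness)
    best_i <- which.min(fit)
    best_theta <- pop[best_i, ]
    best_fit <- fit[best_i]
    history <- numeric(ga_cfg$generations)
    tournament <- function() {
      # binary tournament: the fitter of two random chromosomes
      ij <- sample.int(np, 2, replace = TRUE)
      pop[ij[which.min(fit[ij])], ]
    }
    for (gen in seq_len(ga_cfg$generations)) {
      ord <- order(fit)
      new_pop <- matrix(NA_real_, np, L)
      n_elite <- min(2L, np)
      new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ]
      for (k in seq(n_elite + 1L, length.out = np - n_elite)) {
        child <- if (stats::runif(1) < ga_cfg$crossover_rate) {
          a <- stats::runif(L)
          a * tournament() + (1 - a) * tournament()
        } else {
          tournament()
        }
        mut <- stats::runif(L) < ga_cfg$mutation_rate
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, ga_cfg$mutation_scale)
        new_pop[k, ] <- child
      }
      pop <- new_pop
      fit <- apply(pop, 1, fitness)
      gi <- which.min(fit)
      if (fit[gi] < best_fit) {
        best_fit <- fit[gi]
        best_theta <- pop[gi, ]
      }
      history[gen] <- best_fit
    }
    list(chromosome = best_theta, model = decode(best_theta),
         fitness = best_fit, best_history = history)
  })
}

#' Train a GABP network: GA initialization, BP training, size selection
#'
#' For each candidate hidden size, a genetic algorithm searches for good
#' initial weights and thresholds (scored by internal-validation MSE),
#' back-propagation then trains from that initialization, and the size
#' whose trained network attains the smallest internal-validation MSE is
#' selected (ties toward fewer neurons). With `inputs = "ann3"` (age, sex,
#' creatinine, BMI) and `sizes = 6` this realizes the 4-6-1 topology.
#'
#' @inheritParams select_hidden_size
#' @param ga_cfg a [ga_config()]; per-size GA seeds are derived from its
#'   seed so the whole search is reproducible.
#' @return best trained `ann_model` with the `search` attribute of
#'   [select_hidden_size()].
#' @export
train_gabp <- function(development, internal, inputs, sizes = 1:11,
                       cfg = train_config(), ga_cfg = ga_config()) {
  inputs <- resolve_ann_inputs(inputs)
  init_fn <- function(h) {
    gcfg <- ga_cfg
    if (!is.null(gcfg$seed)) gcfg$seed <- (gcfg$seed + 101L * h) %% .Machine$integer.max
    ga_optimize_init(inputs, h, development, internal,
                     ga_cfg = gcfg, train_cfg = cfg)$model
  }
  select_hidden_size(development, internal, inputs, sizes = sizes,
                     cfg = cfg, init_fn = init_fn)
}
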