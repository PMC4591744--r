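## Three-layer back-propagation network for GFR prediction.
##
## Architecture: input layer (3-6 clinical features), one hidden layer of
## 1-11 sigmoid ("S function") neurons, and a single linear output neuron
## on a [0,1]-scaled GFR range. Inputs are min-max scaled to [0,1] with
## scaling constants computed on the development set only and stored in
## the model, so prediction is self-contained. Sex is coded female = 1
## (matching the equations' female indicator) and creatinine enters on the
## natural-log scale, consistent with the regression development.

ANN_FEATURES <- c("age", "sex", "scr", "bmi", "hba1c", "uacr")

ann_feature_matrix <- function(cohort, inputs) {
  n <- nrow(cohort)
  X <- matrix(NA_real_, n, length(inputs), dimnames = list(NULL, inputs))
  for (f in inputs) {
    v <- switch(f,
                age = cohort$age,
                sex = as.numeric(is_female(cohort$sex)),
                scr = log(cohort$scr),
                bmi = cohort$bmi,
                hba1c = cohort$hba1c,
                uacr = cohort$uacr,
                abort_validation(sprintf("unknown ANN input '%s'", f)))
    if (is.null(v) || anyNA(v)) {
      abort_gfrdm(sprintf("ANN input '%s' missing from the data", f), "gfrdm_evaluation_error")
    }
    X[, f] <- v
  }
  X
}

minmax_scale <- function(X, lo, hi) {
  rng <- hi - lo
  Xs <- sweep(X, 2, lo)
  Xs <- sweep(Xs, 2, ifelse(rng > 0, rng, 1), "/")
  Xs[, rng == 0] <- 0.5  # constant feature: park at mid-range
  Xs
}

#' Construct a three-layer GFR network
#'
#' @param inputs character vector of input features, in order, among
#'   `age`, `sex`, `scr`, `bmi`, `hba1c`, `uacr` (or a variable-set name
#'   `"ann1"`..`"ann8"`, which expands to age, sex, scr plus the set's
#'   covariates).
#' @param n_hidden number of hidden neurons, 1-11.
#' @param W1 `n_hidden x n_inputs` input-to-hidden weights.
#' @param b1 hidden thresholds, length `n_hidden`.
#' @param w2 hidden-to-output weights, length `n_hidden`.
#' @param b2 output threshold (scalar).
#' @param input_lo,input_hi per-input min-max scaling constants.
#' @param output_lo,output_hi training-sGFR range for output scaling.
#' @return object of class `ann_model`.
#' @export
ann_model <- function(inputs, n_hidden, W1, b1, w2, b2,
                      input_lo, input_hi, output_lo, output_hi) {
  inputs <- resolve_ann_inputs(inputs)
  p <- length(inputs)
  stopifnot(n_hidden >= 1, n_hidden <= 11,
            is.matrix(W1), dim(W1) == c(n_hidden, p),
            length(b1) == n_hidden, length(w2) == n_hidden, length(b2) == 1,
            length(input_lo) == p, length(input_hi) == p,
            all(is.finite(c(W1, b1, w2, b2))))
  structure(list(inputs = inputs, n_hidden = as.integer(n_hidden),
                 W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2),
                 input_lo = stats::setNames(as.numeric(input_lo), inputs),
                 input_hi = stats::setNames(as.numeric(input_hi), inputs),
                 output_lo = output_lo, output_hi = output_hi),
            class = "ann_model")
}

resolve_ann_inputs <- function(inputs) {
  if (is.character(inputs) && length(inputs) == 1 && grepl("^(eq|ann)[1-8]$", inputs)) {
    return(c("age", "sex", "scr", resolve_vset(inputs)))
  }
  bad <- setdiff(inputs, ANN_FEATURES)
  if (length(bad)) abort_validation(sprintf("unknown ANN input(s): %s", paste(bad, collapse = ", ")))
  inputs
}

#' Randomly initialized network with scaling from a development cohort
#'
#' Weights and thresholds drawn uniformly on \[-0.5, 0.5\]; min-max input
#' and output scaling computed on the development records.
#'
#' @inheritParams ann_model
#' @param development a `cohort` with `sgfr` and the input features.
#' @param seed integer seed (`NULL` = current RNG stream).
#' @return an `ann_model`.
#' @export
random_ann <- function(inputs, n_hidden, development, seed = NULL) {
  inputs <- resolve_ann_inputs(inputs)
  X <- ann_feature_matrix(development, inputs)
  y <- development$sgfr
  if (anyNA(y)) abort_gfrdm("development records must carry sgfr", "gfrdm_missing_field_error")
  p <- length(inputs)
  with_seed(seed, {
    L <- n_hidden * p + 2 * n_hidden + 1
    theta <- stats::runif(L, -0.5, 0.5)
    ann_from_chromosome(theta, inputs, n_hidden,
                        apply(X, 2, min), apply(X, 2, max), min(y), max(y))
  })
}

chromosome_length <- function(p, h) h * p + 2 * h + 1

ann_from_chromosome <- function(theta, inputs, n_hidden, input_lo, input_hi,
                                output_lo, output_hi) {
  p <- length(inputs)
  stopifnot(length(theta) == chromosome_length(p, n_hidden))
  i <- 0
  W1 <- matrix(theta[seq_len(n_hidden * p)], n_hidden, p); i <- n_hidden * p
  b1 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  w2 <- theta[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- theta[i + 1]
  ann_model(inputs, n_hidden, W1, b1, w2, b2, input_lo, input_hi, output_lo, output_hi)
}

ann_chromosome <- function(model) {
  c(as.vector(model$W1), model$b1, model$w2, model$b2)
}

## forward pass on an already-scaled design matrix; returns scaled output
ann_forward_scaled <- function(model, Xs) {
  H <- sigmoid(Xs %*% t(model$W1) + matrix(model$b1, nrow(Xs), model$n_hidden, byrow = TRUE))
  list(H = H, yhat = as.vector(H %*% model$w2 + model$b2))
}

#' Predict GFR with a trained network
#'
#' Scales the record's features with the stored development-set min-max
#' constants, propagates through the sigmoid hidden layer and the linear
#' output neuron, and inverse-scales to mL/min/1.73 m^2.
#'
#' @param object an [ann_model()].
#' @param newdata `cohort` or data frame carrying the model's inputs.
#' @param ... unused.
#' @return eGFR vector, mL/min/1.73 m^2.
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- ann_feature_matrix(newdata, object$inputs)
  Xs <- minmax_scale(X, object$input_lo, object$input_hi)
  ys <- ann_forward_scaled(object, Xs)$yhat
  object$output_lo + ys * (object$output_hi - object$output_lo)
}

## Analytic gradients of the full-batch MSE (scaled output) w.r.t. all
## weights and thresholds. e = yhat - y on the scaled range.
ann_gradients <- function(model, Xs, ys) {
  n <- nrow(Xs)
  fw <- ann_forward_scaled(model, Xs)
  e <- fw$yhat - ys
  d_out <- 2 * e / n                            # dMSE/dyhat
  g_b2 <- sum(d_out)
  g_w2 <- as.vector(crossprod(fw$H, d_out))
  Dh <- (d_out %o% model$w2) * fw$H * (1 - fw$H) # n x h
  g_b1 <- colSums(Dh)
  g_W1 <- crossprod(Dh, Xs)                      # h x p
  list(W1 = g_W1, b1 = g_b1, w2 = g_w2, b2 = g_b2, mse = mean(e^2))
}

#' Training configuration for back-propagation
#'
#' Full-batch gradient descent with momentum on the development-set MSE of
#' the scaled output.
#'
#' @param learning_rate step size (> 0).
#' @param momentum momentum coefficient in \[0, 1).
#' @param max_epochs maximum epochs (>= 1).
#' @param patience epochs without internal-validation improvement before
#'   early stop (`Inf` disables).
#' @param seed seed for any randomized initialization done by callers.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.05, momentum = 0.9,
                         max_epochs = 2000, patience = 200, seed = NULL) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), patience = patience,
                 seed = seed), class = "train_config")
}

#' Train a network by back-propagation with internal-validation snapshots
#'
#' Runs full-batch gradient descent with momentum on the development-set
#' MSE and returns the epoch snapshot with the lowest internal-validation
#' MSE (the model-selection rule: smallest mean square error in the
#' internal validation set is best). Deterministic given the model and
#' data — training itself draws no random numbers.
#'
#' @param model starting [ann_model()].
#' @param development,internal `cohort`s with `sgfr` and the model inputs.
#' @param cfg a [train_config()].
#' @return the best-snapshot `ann_model`, with an attribute `trace`
#'   (list of per-epoch `dev_mse`, `internal_mse` and `best_epoch`).
#' @export
train_bp <- function(model, development, internal, cfg = train_config()) {
  if (nrow(development) == 0 || nrow(internal) == 0) {
    abort_gfrdm("development and internal sets must be non-empty", "gfrdm_insufficient_data_error")
  }
  sets <- lapply(list(dev = development, int = internal), function(d) {
    if (anyNA(d$sgfr)) abort_gfrdm("records must carry sgfr", "gfrdm_missing_field_error")
    X <- ann_feature_matrix(d, model$inputs)
    list(Xs = minmax_scale(X, model$input_lo, model$input_hi),
         ys = (d$sgfr - model$output_lo) / (model$output_hi - model$output_lo))
  })
  internal_mse <- function(m) {
    mean((ann_forward_scaled(m, sets$int$Xs)$yhat - sets$int$ys)^2)
  }
  vel <- list(W1 = model$W1 * 0, b1 = model$b1 * 0, w2 = model$w2 * 0, b2 = 0)
  best <- model
  best_mse <- internal_mse(model)
  best_epoch <- 0L
  dev_trace <- int_trace <- numeric(cfg$max_epochs)
  for (epoch in seq_len(cfg$max_epochs)) {
    g <- ann_gradients(model, sets$dev$Xs, sets$dev$ys)
    if (!is.finite(g$mse)) {
      abort_gfrdm("training loss became non-finite; try a smaller learning_rate",
                  "gfrdm_training_error")
    }
    for (nm in c("W1", "b1", "w2", "b2")) {
      vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[nm]]
      model[[nm]] <- model[[nm]] + vel[[nm]]
    }
    dev_trace[epoch] <- g$mse
    im <- internal_mse(model)
    int_trace[epoch] <- im
    if (is.finite(im) && im < best_mse) {
      best_mse <- im
      best <- model
      best_epoch <- epoch
    }
    if (epoch - best_epoch >= cfg$patience) {
      dev_trace <- dev_trace[seq_len(epoch)]
      int_trace <- int_trace[seq_len(epoch)]
      break
    }
  }
  attr(best, "trace") <- list(dev_mse = dev_trace, internal_mse = int_trace,
                              best_epoch = best_epoch, best_internal_mse = best_mse)
  best
}

#' Hidden-layer size search by internal-validation MSE
#'
#' Trains one network per candidate hidden size and returns the one with
#' the smallest internal-validation MSE; ties break toward fewer neurons.
#' Initial weights come from `init_fn(n_hidden)` (default: seeded random
#' initialization, seed derived per size from `cfg$seed`).
#'
#' @param development,internal `cohort`s.
#' @param inputs ANN inputs or variable-set name (see [ann_model()]).
#' @param sizes candidate hidden sizes (subset of 1..11).
#' @param cfg a [train_config()].
#' @param init_fn optional `function(n_hidden) -> ann_model` supplying the
#'   starting network per size.
#' @return best trained `ann_model`; attribute `search` is a data frame of
#'   size vs internal MSE.
#' @export
select_hidden_size <- function(development, internal, inputs, sizes = 1:11,
                               cfg = train_config(), init_fn = NULL) {
  if (!length(sizes)) abort_validation("sizes must be non-empty")
  sizes <- sort(unique(as.integer(sizes)))
  inputs <- resolve_ann_inputs(inputs)
  if (is.null(init_fn)) {
    init_fn <- function(h) {
      sd <- if (is.null(cfg$seed)) NULL else cfg$seed + h
      random_ann(inputs, h, development, seed = sd)
    }
  }
  fits <- lapply(sizes, function(h) train_bp(init_fn(h), development, internal, cfg))
  mses <- vapply(fits, function(m) attr(m, "trace")$best_internal_mse, numeric(1))
  best <- fits[[which.min(mses)]]  # which.min takes the first: fewest neurons on ties
  attr(best, "search") <- data.frame(n_hidden = sizes, internal_mse = mses)
  best
}
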