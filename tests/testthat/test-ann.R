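test_that("zero-weight networks predict the training-range midpoint", {
  dev <- make_sim_cohort(100, seed = 1)
  m <- ann_model("ann1", 3, W1 = matrix(0, 3, 3), b1 = rep(0, 3),
                 w2 = rep(0, 3), b2 = 0.5,
                 input_lo = c(18, 0, log(0.2)), input_hi = c(90, 1, log(5)),
                 output_lo = 20, output_hi = 120)
  expect_equal(predict(m, dev), rep((20 + 120) / 2, 100))
})

test_that("sigmoid(0) hidden units give 0.5 * w2 + b2 on the scaled range", {
  m <- ann_model(c("age", "scr"), 1, W1 = matrix(0, 1, 2), b1 = 0,
                 w2 = 0.8, b2 = 0.05,
                 input_lo = c(20, log(0.4)), input_hi = c(80, log(4)),
                 output_lo = 10, output_hi = 130)
  pred <- predict(m, data.frame(sex = "M", age = 47, scr = 1.3))
  expect_equal(pred, 10 + (0.5 * 0.8 + 0.05) * 120, tolerance = 1e-12)
})

test_that("forward pass matches a by-hand two-layer computation", {
  m <- make_hand_ann()
  rec <- data.frame(sex = "F", age = 50, scr = 1.0)
  x1 <- (50 - 20) / (80 - 20)
  x2 <- (log(1.0) - log(0.4)) / (log(4) - log(0.4))
  h <- 1 / (1 + exp(-(0.4 * x1 - 0.3 * x2 + 0.1)))
  y <- 10 + (0.8 * h + 0.05) * 120
  expect_equal(predict(m, rec), y, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  for (rep in 1:5) {
    p <- sample(2:4, 1); h <- sample(1:4, 1); n <- 12
    inputs <- sample(c("age", "sex", "scr", "bmi", "hba1c", "uacr"), p)
    Xs <- matrix(runif(n * p), n, p)
    ys <- runif(n)
    theta <- runif(gfrdm:::chromosome_length(p, h), -1, 1)
    m <- gfrdm:::ann_from_chromosome(theta, inputs, h, rep(0, p), rep(1, p), 0, 1)
    g <- gfrdm:::ann_gradients(m, Xs, ys)
    g_vec <- c(as.vector(g$W1), g$b1, g$w2, g$b2)
    f <- function(th) {
      mm <- gfrdm:::ann_from_chromosome(th, inputs, h, rep(0, p), rep(1, p), 0, 1)
      mean((gfrdm:::ann_forward_scaled(mm, Xs)$yhat - ys)^2)
    }
    eps <- 1e-6
    fd <- vapply(seq_along(theta), function(i) {
      tp <- tm <- theta; tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      (f(tp) - f(tm)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(g_vec - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("training drives development MSE far down on a self-realizable target", {
  dev <- make_sim_cohort(200, seed = 3)
  int <- make_sim_cohort(100, seed = 4)
  gen <- random_ann(c("age", "sex", "scr"), 3, dev, seed = 11)
  dev$sgfr <- predict(gen, dev)
  int$sgfr <- predict(gen, int)
  start <- random_ann(c("age", "sex", "scr"), 3, dev, seed = 12)
  trained <- train_bp(start, dev, int, train_config(max_epochs = 2000, patience = Inf))
  tr <- attr(trained, "trace")
  expect_lt(min(tr$dev_mse), 0.01 * tr$dev_mse[1])
})

test_that("zero learning rate leaves weights untouched; training is deterministic", {
  dev <- make_sim_cohort(80, seed = 5)
  int <- make_sim_cohort(40, seed = 6)
  m <- random_ann("ann3", 2, dev, seed = 9)
  frozen <- train_bp(m, dev, int, train_config(learning_rate = 0, max_epochs = 50, patience = Inf))
  expect_identical(frozen$W1, m$W1)
  expect_equal(diff(range(attr(frozen, "trace")$dev_mse)), 0)

  a <- train_bp(m, dev, int, train_config(max_epochs = 100, patience = Inf))
  b <- train_bp(m, dev, int, train_config(max_epochs = 100, patience = Inf))
  expect_identical(a$W1, b$W1)
  expect_identical(attr(a, "trace")$internal_mse, attr(b, "trace")$internal_mse)
})

test_that("record order does not change full-batch training", {
  dev <- make_sim_cohort(80, seed = 15)
  int <- make_sim_cohort(40, seed = 16)
  m <- random_ann("ann1", 3, dev, seed = 2)
  perm <- sample(nrow(dev))
  a <- train_bp(m, dev, int, train_config(max_epochs = 60, patience = Inf))
  b <- train_bp(m, dev[perm, ], int, train_config(max_epochs = 60, patience = Inf))
  expect_equal(a$W1, b$W1, tolerance = 1e-12)
})

test_that("exploding steps raise a training error that advises a smaller rate", {
  dev <- make_sim_cohort(60, seed = 25)
  int <- make_sim_cohort(30, seed = 26)
  m <- random_ann("ann1", 4, dev, seed = 3)
  expect_error(train_bp(m, dev, int, train_config(learning_rate = 1e6, max_epochs = 200, patience = Inf)),
               "learning_rate", class = "gfrdm_training_error")
})

test_that("hidden-size selection returns the internal-MSE argmin, ties to fewer neurons", {
  dev <- make_sim_cohort(150, seed = 33)
  int <- make_sim_cohort(80, seed = 34)
  gen <- random_ann("ann1", 3, dev, seed = 5)
  dev$sgfr <- predict(gen, dev); int$sgfr <- predict(gen, int)
  cfg <- train_config(max_epochs = 150, patience = Inf, seed = 77)
  best <- select_hidden_size(dev, int, "ann1", sizes = c(1, 3, 5), cfg = cfg)
  srch <- attr(best, "search")
  expect_equal(attr(best, "trace")$best_internal_mse, min(srch$internal_mse))
  expect_equal(best$n_hidden, srch$n_hidden[which.min(srch$internal_mse)])

  # degenerate single-size search
  only4 <- select_hidden_size(dev, int, "ann3", sizes = 4, cfg = cfg)
  expect_equal(only4$n_hidden, 4L)
  expect_equal(length(only4$inputs), 4L)

  # forced exact tie: the size-5 start pads the size-3 network with dead
  # neurons and training is frozen (lr = 0), so internal MSEs are equal and
  # the tie must break toward fewer neurons
  base <- random_ann("ann1", 3, dev, seed = 21)
  pad_init <- function(h) {
    if (h == 3) return(base)
    W1 <- rbind(base$W1, matrix(0, h - 3, ncol(base$W1)))
    ann_model(base$inputs, h, W1, b1 = c(base$b1, rep(0, h - 3)),
              w2 = c(base$w2, rep(0, h - 3)), b2 = base$b2,
              input_lo = base$input_lo, input_hi = base$input_hi,
              output_lo = base$output_lo, output_hi = base$output_hi)
  }
  frozen_cfg <- train_config(learning_rate = 0, max_epochs = 5, patience = Inf)
  tie <- select_hidden_size(dev, int, "ann1", sizes = c(3, 5), cfg = frozen_cfg,
                            init_fn = pad_init)
  expect_equal(tie$n_hidden, 3L)
})

test_that("predictions stay finite within the affine range of the output layer", {
  dev <- make_sim_cohort(50, seed = 43)
  m <- random_ann("ann8", 11, dev, seed = 8)
  pred <- predict(m, dev)
  expect_true(all(is.finite(pred)))
  # sigmoid outputs lie in (0,1): bound from the output layer's weights
  bound_hi <- m$output_lo + (sum(pmax(m$w2, 0)) + m$b2) * (m$output_hi - m$output_lo)
  bound_lo <- m$output_lo + (sum(pmin(m$w2, 0)) + m$b2) * (m$output_hi - m$output_lo)
  expect_true(all(pred <= bound_hi & pred >= bound_lo))
})

test_that("model round trip through the flat text format is exact", {
  dev <- make_sim_cohort(60, seed = 51)
  m <- random_ann("ann3", 5, dev, seed = 14)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back, m, tolerance = 0)

  sm <- spline_model(4.85, -0.3, -1.1, age_coef = -0.006, female_coef = 0.02,
                     covariate_coefs = c(bmi = 0.004))
  write_model(sm, path)
  expect_equal(read_model(path), sm, tolerance = 0)
})
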