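test_that("identical models give a degenerate Wilcoxon comparison with p = 1", {
  set.seed(21)
  sgfr <- runif(30, 30, 120)
  p <- structure(data.frame(sgfr = sgfr, a = sgfr * 1.1, b = sgfr * 1.1),
                 class = c("paired_predictions", "data.frame"))
  res <- compare_bias_wilcoxon(p, "a", "b")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("all-positive signs at n = 6 give the exact sign-pattern tail", {
  # one-sided tail is 1/2^6; two-sided doubles it
  sgfr <- rep(100, 6)
  a <- 100 + c(5, 7, 9, 11, 13, 15)  # |err_a| > |err_b| for every pair
  b <- 100 + c(1, 2, 3, 4, 5, 6)     # differences 4..9, tie-free
  p <- structure(data.frame(sgfr = sgfr, a = a, b = b),
                 class = c("paired_predictions", "data.frame"))
  res <- compare_bias_wilcoxon(p, "a", "b")
  expect_true(res$exact)
  expect_equal(res$p_value, 2 / 2^6)
})

test_that("exact Wilcoxon p-values match full sign-pattern enumeration for n <= 10", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    d <- round(rnorm(n, 0.2, 1), 3)
    d <- d + (d == 0) * 0.05           # keep pairs nonzero
    while (anyDuplicated(abs(d))) d <- d + runif(n, 0, 1e-4)
    res <- gfrdm:::wilcoxon_signed_rank(d)
    expect_true(res$exact)
    expect_equal(res$p_value, enum_wilcoxon(d), tolerance = 1e-12)
  }
})

test_that("exact and asymptotic Wilcoxon paths agree near the crossover size", {
  set.seed(23)
  for (i in 1:10) {
    d <- rnorm(25, 0.3, 1)
    exact <- gfrdm:::wilcoxon_signed_rank(d, exact_max = 25)
    asym <- gfrdm:::wilcoxon_signed_rank(d, exact_max = 0)
    expect_true(exact$exact); expect_false(asym$exact)
    expect_lt(abs(exact$p_value - asym$p_value), 0.01)
  }
})

test_that("McNemar discordance of 8 vs 0 gives the exact doubled binomial tail", {
  # model a within 30 % on all records; model b misses 8 of them
  sgfr <- rep(100, 10)
  a <- rep(100, 10)
  b <- c(100, 100, rep(140, 8))
  p <- structure(data.frame(sgfr = sgfr, a = a, b = b),
                 class = c("paired_predictions", "data.frame"))
  res <- compare_accuracy_mcnemar(p, "a", "b")
  expect_true(res$exact)
  expect_equal(res$p_value, 2 * (1 / 2)^8)  # 0.0078125
  expect_equal(res$statistic, 8)

  balanced <- structure(
    data.frame(sgfr = rep(100, 10),
               a = c(rep(100, 5), rep(140, 5)),
               b = c(rep(140, 5), rep(100, 5))),
    class = c("paired_predictions", "data.frame"))
  expect_equal(compare_accuracy_mcnemar(balanced, "a", "b")$p_value, 1)

  same <- structure(data.frame(sgfr = rep(100, 4), a = rep(100, 4), b = rep(100, 4)),
                    class = c("paired_predictions", "data.frame"))
  res_d <- compare_accuracy_mcnemar(same, "a", "b")
  expect_true(res_d$degenerate)
  expect_equal(res_d$p_value, 1)
})

test_that("exact McNemar matches binomial tail sums; asymptotic matches mcnemar.test", {
  mk <- function(b, cc) {
    n_within_both <- 2
    n <- n_within_both + b + cc
    structure(data.frame(
      sgfr = rep(100, n),
      a = c(rep(100, n_within_both), rep(100, b), rep(140, cc)),
      b = c(rep(100, n_within_both), rep(140, b), rep(100, cc))),
      class = c("paired_predictions", "data.frame"))
  }
  set.seed(24)
  for (i in 1:20) {
    b <- sample(0:12, 1); cc <- sample(0:12, 1)
    if (b + cc == 0) next
    res <- compare_accuracy_mcnemar(mk(b, cc), "a", "b")
    expect_equal(res$p_value, enum_mcnemar(b, cc), tolerance = 1e-12)
  }
  # large discordance: chi-square with continuity correction
  res <- compare_accuracy_mcnemar(mk(20, 10), "a", "b")
  expect_false(res$exact)
  tab <- matrix(c(2, 10, 20, 0), 2)
  expect_equal(res$p_value, mcnemar.test(tab, correct = TRUE)$p.value, tolerance = 1e-12)
})

test_that("cohort comparisons pick the right test and the exact Mann-Whitney enumerates", {
  a <- make_sim_cohort(8, seed = 1)
  expect_equal(compare_cohorts(a, a, "scr"), 1)  # identical groups

  # n = 3 vs 3: enumeration over all 20 assignments
  x <- as_cohort(data.frame(sex = "F", age = 50, scr = c(0.5, 0.9, 1.4)))
  y <- as_cohort(data.frame(sex = "F", age = 50, scr = c(2.1, 2.5, 3.0)))
  p <- compare_cohorts(x, y, "scr")
  expect_equal(p, 2 / 20)  # most extreme separation: 2 of 20 assignments

  big_a <- make_sim_cohort(60, seed = 2)
  big_b <- make_sim_cohort(60, seed = 3)
  expect_equal(compare_cohorts(big_a, big_b, "uacr"),
               wilcox.test(big_a$uacr, big_b$uacr, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(compare_cohorts(big_a, big_b, "age"),
               t.test(big_a$age, big_b$age)$p.value)
  expect_error(compare_cohorts(big_a, big_b, "nope"), class = "gfrdm_key_error")
})

test_that("the t-test path holds its nominal type-I error on simulated normals", {
  set.seed(25)
  reps <- 1000
  rej <- mean(replicate(reps, {
    a <- as_cohort(data.frame(sex = "F", age = rnorm(20, 60, 8), scr = 1))
    b <- as_cohort(data.frame(sex = "F", age = rnorm(20, 60, 8), scr = 1))
    compare_cohorts(a, b, "age") < 0.05
  }))
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rej - 0.05), 3 * se)
})
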