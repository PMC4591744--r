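test_that("zero-noise cohorts are recovered exactly by least squares", {
  truth <- spline_model(intercept = 4.85, slope_below = -0.32, slope_above = -1.15,
                        age_coef = -0.0065, female_coef = 0.025,
                        covariate_coefs = c(bmi = 0.003, hba1c = -0.008, uacr = -2e-4))
  ch <- make_sim_cohort(400, noise_sigma = 0, seed = 21, truth = truth)
  fit <- fit_spline_equation(ch, "eq8")
  expect_equal(truth_coef_vector(fit$model)[names(truth_coef_vector(truth))],
               truth_coef_vector(truth), tolerance = 1e-9)
  expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$diagnostics$residual_sd, 0, tolerance = 1e-9)
})

test_that("coefficient estimates are unbiased across replicate noisy fits", {
  set.seed(123)
  truth <- default_truth_model()
  est <- replicate(60, {
    ch <- make_sim_cohort(400, noise_sigma = 0.2, seed = NULL, truth = truth)
    truth_coef_vector(fit_spline_equation(ch, "eq1")$model)
  })
  bias_hat <- rowMeans(est) - truth_coef_vector(truth)
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_true(all(abs(bias_hat) < 4 * mc_se + 1e-10))
})

test_that("OLS residuals are orthogonal to every design column", {
  ch <- make_sim_cohort(300, noise_sigma = 0.2, seed = 13)
  fit <- fit_spline_equation(ch, "eq5")
  resid <- log(ch$sgfr) - log(predict(fit$model, ch))
  female <- as.numeric(ch$sex == "F")
  kappa <- ifelse(female == 1, 0.7, 0.8)
  ls <- log(ch$scr / kappa)
  X <- cbind(1, pmin(ls, 0), pmax(ls, 0), ch$age, female, ch$hba1c, ch$bmi)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8 * nrow(ch))
})

test_that("richer variable sets never increase the residual sum of squares", {
  ch <- make_sim_cohort(500, noise_sigma = 0.3, seed = 17)
  rss <- function(vset) {
    fit <- fit_spline_equation(ch, vset)
    sum((log(ch$sgfr) - log(predict(fit$model, ch)))^2)
  }
  expect_lte(rss("eq8"), rss("eq1") + 1e-10)
})

test_that("refits are bit-identical and degenerate designs error", {
  ch <- make_sim_cohort(200, seed = 19)
  a <- fit_spline_equation(ch, "eq3")
  b <- fit_spline_equation(ch, "eq3")
  expect_identical(truth_coef_vector(a$model), truth_coef_vector(b$model))

  flat <- ch
  flat$scr <- 0.5  # spline columns constant -> collinear
  expect_error(fit_spline_equation(flat, "eq1"),
               class = "gfrdm_collinearity_error")

  expect_error(fit_spline_equation(ch[0, ], "eq1"),
               class = "gfrdm_insufficient_data_error")
  expect_error(fit_spline_equation(ch[1:4, ], "eq1"),
               class = "gfrdm_insufficient_data_error")
})

test_that("missing outcome or covariate fields fail loudly, never imputed", {
  ch <- make_sim_cohort(100, seed = 23)
  ch$hba1c[5] <- NA
  expect_error(fit_spline_equation(ch, "eq2"), "hba1c",
               class = "gfrdm_missing_field_error")
  ch2 <- make_sim_cohort(100, seed = 23)
  ch2$sgfr[1] <- NA
  expect_error(fit_spline_equation(ch2, "eq1"), "sgfr",
               class = "gfrdm_missing_field_error")
})

test_that("fit_all_equations fits eight sets, or skips sets with wholly absent covariates", {
  ch <- make_sim_cohort(300, seed = 29)
  fits <- fit_all_equations(ch)
  expect_named(fits, paste0("eq", 1:8))

  no_uacr <- ch
  no_uacr$uacr <- NA_real_
  w <- capture_warnings(fits2 <- fit_all_equations(no_uacr))
  expect_length(w, 4)  # eq4, eq6, eq7, eq8 skipped
  expect_true(all(grepl("uacr", w)))
  expect_named(fits2, c("eq1", "eq2", "eq3", "eq5"))
})

test_that("development/internal labels control which records are fitted", {
  ch <- make_sim_cohort(300, noise_sigma = 0.1, seed = 31, split_seed = 2)
  dev_only <- fit_spline_equation(ch, "eq1")
  expect_equal(dev_only$diagnostics$n_used, 200)
  pooled <- fit_spline_equation(ch, "eq1", pool_internal = TRUE)
  expect_equal(pooled$diagnostics$n_used, 300)
})

test_that("smoothing-spline diagnostic brackets the generating slopes", {
  truth <- spline_model(intercept = 4.9, slope_below = -0.3, slope_above = -1.2)
  ch <- make_sim_cohort(4000, noise_sigma = 0.02, seed = 37, truth = truth)
  curves <- smoothing_spline_diagnostic(ch, df = 6)
  for (sx in c("F", "M")) {
    cv <- curves[[sx]]
    k <- log(if (sx == "F") 0.7 else 0.8)
    local_slope <- function(region) {
      d <- cv[region, ]
      coef(lm(log_sgfr_fit ~ log_scr, d))[2]
    }
    far_below <- cv$log_scr < k - 0.4
    far_above <- cv$log_scr > k + 0.4
    expect_equal(unname(local_slope(far_below)), -0.3, tolerance = 0.15)
    expect_equal(unname(local_slope(far_above)), -1.2, tolerance = 0.15)
  }
})

test_that("smoothing diagnostic is deterministic, flat on constant data, and guards small n", {
  ch <- make_sim_cohort(200, seed = 41)
  a <- smoothing_spline_diagnostic(ch, df = 5)
  b <- smoothing_spline_diagnostic(ch, df = 5)
  expect_identical(a, b)

  flat <- make_sim_cohort(200, seed = 41)
  flat$sgfr <- 80
  fl <- smoothing_spline_diagnostic(flat, df = 5)
  expect_equal(fl$M$log_sgfr_fit, rep(log(80), nrow(fl$M)))

  expect_error(smoothing_spline_diagnostic(make_sim_cohort(10, seed = 1)),
               class = "gfrdm_insufficient_data_error")
})
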