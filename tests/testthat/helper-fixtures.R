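# shared fixtures, built in code

# small hand-written cohort with all fields present
make_tiny_cohort <- function() {
  as_cohort(data.frame(
    id = c("a", "b", "c", "d"),
    sex = c("F", "M", "M", "F"),
    age = c(50, 60, 70, 45),
    scr = c(0.7, 0.9, 1.6, 0.6),
    bmi = c(24, 27, 30, 22),
    hba1c = c(7.5, 8.5, 9.0, 6.5),
    uacr = c(20, 45, 350, 10),
    sgfr = c(95, 85, 40, 110)))
}

# simulated cohort from a known truth, optionally split
make_sim_cohort <- function(n, noise_sigma = 0.05, seed = 42, split_seed = NULL,
                            truth = default_truth_model()) {
  ch <- generate_cohort(cohort_sim_config(n = n, noise_sigma = noise_sigma,
                                          truth = truth, seed = seed))
  if (!is.null(split_seed)) ch <- split_cohort(ch, 2 / 3, seed = split_seed)
  ch
}

truth_coef_vector <- function(m) {
  c(intercept = m$intercept, slope_below = m$slope_below,
    slope_above = m$slope_above, age_coef = m$age_coef,
    female_coef = m$female_coef, m$covariate_coefs)
}

# a fixed hand-set 1-hidden-unit network on two inputs for forward checks
make_hand_ann <- function() {
  ann_model(inputs = c("age", "scr"), n_hidden = 1,
            W1 = matrix(c(0.4, -0.3), 1, 2), b1 = 0.1, w2 = 0.8, b2 = 0.05,
            input_lo = c(20, log(0.4)), input_hi = c(80, log(4)),
            output_lo = 10, output_hi = 130)
}

# brute-force metric re-implementations, independent of the package path
brute_bias <- function(egfr, sgfr) {
  d <- sort(egfr - sgfr)
  n <- length(d)
  if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
}
brute_iqr <- function(egfr, sgfr) {
  d <- egfr - sgfr
  q <- function(p) {
    # type-7 linear interpolation written out longhand
    s <- sort(d)
    h <- (length(s) - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
  }
  q(0.75) - q(0.25)
}
brute_p30 <- function(egfr, sgfr) {
  100 * sum(abs(egfr - sgfr) / sgfr <= 0.3) / length(sgfr)
}

# exact Wilcoxon signed-rank two-sided p by enumeration of all sign patterns
enum_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# exact two-sided McNemar p by binomial tail sums
enum_mcnemar <- function(b, cc) {
  n <- b + cc
  probs <- dbinom(0:n, n, 0.5)
  p_obs <- dbinom(b, n, 0.5)
  sum(probs[probs <= p_obs + 1e-12])
}
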