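# Independent closed-form oracles used to freeze expected values.

# Normal-equations least squares, independent of ols_fit()'s lm route.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  p <- 2 * stats::pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r_squared = r2, p_value = p)
}

# Direct evaluation of the kinetics forward model, written independently of
# predict_r_ratio().
oracle_r_ratio <- function(t, m, n, c_p, pi_total, ratio = 10) {
  exp(log(m) - n * log(t + exp(log(m) / n))) + ratio * c_p / pi_total
}

zero_noise_pot <- function(seed = 1L) {
  simulate_pot_experiment(noise_cv_p = 0, noise_cv_activity = 0,
                          biological_cv = 0, seed = seed)
}
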