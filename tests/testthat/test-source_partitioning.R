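test_that("ols_fit matches the normal-equations oracle", {
  # exact line and constant response
  f <- ols_fit(1:5, 2 * (1:5) + 3)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 3)
  expect_equal(f$r_squared, 1)
  f0 <- ols_fit(1:5, rep(4, 5))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  # seeded random data against the closed form
  set.seed(11)
  x <- rnorm(10); y <- 1.5 * x + rnorm(10, sd = 0.3)
  f <- ols_fit(x, y); o <- oracle_ols(x, y)
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(f$r_squared, o$r_squared, tolerance = 1e-10)
  expect_equal(f$p_value, o$p_value, tolerance = 1e-10)
  expect_error(ols_fit(c(1, 2), c(1, 2)), "3")
  expect_error(ols_fit(rep(1, 5), 1:5), "variance")
})

test_that("seed model fits, predicts, and clamps", {
  u <- c(2, 5, 9, 12)
  m <- fit_seed_model(data.frame(uptake = u, pdf_seed = 0.05 * u + 0.4))
  expect_equal(m$a, 0.05)
  expect_equal(m$b, 0.4)
  expect_equal(m$r_squared, 1)
  # collinear third point changes nothing
  m3 <- fit_seed_model(data.frame(uptake = c(2, 5, 8),
                                  pdf_seed = 0.05 * c(2, 5, 8) + 0.4))
  expect_equal(c(m3$a, m3$b), c(m$a, m$b))
  # noisy recovery against the generator truth
  set.seed(7)
  u <- runif(20, 2, 12)
  noisy <- fit_seed_model(data.frame(
    uptake = u, pdf_seed = 0.04 * u + 0.5 + rnorm(20, sd = 0.05)))
  expect_lt(abs(noisy$a - 0.04), 0.02)

  expect_equal(as.numeric(predict_seed_p(10, seed_p_model(0, 0.7))), 0.7)
  expect_equal(as.numeric(predict_seed_p(10, seed_p_model(0.05, 0.4))), 0.9)
  p <- predict_seed_p(0, seed_p_model(0.05, -0.1))
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "clamped"))
  expect_error(fit_seed_model(data.frame(uptake = 1:2, pdf_seed = 1:2)), "3")
})

test_that("direct partition follows the SA ratio and flags impossibilities", {
  expect_equal(as.numeric(pdf_fertilizer_direct(0, 100, 8)), 0)
  expect_equal(as.numeric(pdf_fertilizer_direct(100, 100, 8)), 8)
  # the directly labeled mineral control: share 36.9% of 10.3 at dose 30
  pdf <- as.numeric(pdf_fertilizer_direct(0.369 * 4e4, 4e4, 10.3))
  expect_equal(pdf, 3.8007, tolerance = 1e-10)
  expect_equal(fertilizer_recovery(pdf, 30), 12.7, tolerance = 0.1)
  expect_true(attr(pdf_fertilizer_direct(110, 100, 8), "impossible_ratio"))
  expect_error(pdf_fertilizer_direct(10, 0, 8), "sa_fert")
  # strict monotonicity in sa_plant
  sa <- seq(10, 90, by = 10)
  vals <- as.numeric(pdf_fertilizer_direct(sa, 100, 8))
  expect_true(all(diff(vals) > 0))
})

test_that("indirect partition arithmetic and its reference", {
  m0 <- seed_p_model(0, 0)
  expect_equal(sa_noP_reference(
    data.frame(activity = 600, uptake = 6.0), seed_p_model(0.05, 0.3)),
    600 / 5.4, tolerance = 1e-12)
  expect_equal(sa_noP_reference(
    data.frame(activity = 600, uptake = 6.0), m0), 100)
  expect_equal(sa_noP_reference(
    data.frame(activity = c(600, 600), uptake = c(6, 6)), m0), 100)
  expect_error(sa_noP_reference(
    data.frame(activity = 600, uptake = 0.2), seed_p_model(0.05, 0.3)),
    "degenerate")

  expect_equal(pdf_soil_indirect(100, 100, 10.2, 0.95), 9.25)
  expect_equal(pdf_soil_indirect(0, 100, 10.2, 0.95), 0)
  expect_equal(pdf_soil_indirect(55, 100, 10.2, 0.95), 5.0875)
  expect_error(pdf_soil_indirect(55, 0, 10.2, 0.95), "sa_noP")

  expect_equal(as.numeric(pdf_fertilizer_indirect(10.2, 5.0875, 0.95)),
               4.1625)
  expect_equal(as.numeric(pdf_fertilizer_indirect(10, 9.3, 0.7)), 0)
  neg <- pdf_fertilizer_indirect(6.0, 5.5, 0.7)
  expect_equal(as.numeric(neg), -0.2)
  expect_true(attr(neg, "negative"))
})

test_that("recovery and RAE ratios", {
  expect_equal(fertilizer_recovery(0, 30), 0)
  expect_equal(fertilizer_recovery(0.424 * 10.2, 30), 14.4, tolerance = 0.1)
  expect_error(fertilizer_recovery(1, 0), "dose")
  expect_equal(relative_agronomic_efficiency(14.4, 14.4), 100)
  expect_equal(relative_agronomic_efficiency(2.3, 14.4), 16.0,
               tolerance = 0.5)
  expect_equal(relative_agronomic_efficiency(10.7, 16.3), 65.6,
               tolerance = 0.5)
  expect_error(relative_agronomic_efficiency(10, 0), "reference")
})

test_that("partition_experiment recovers zero-noise truth exactly", {
  pot <- zero_noise_pot()
  sm <- seed_p_model(pot$truth$seed_a, pot$truth$seed_b)
  part <- partition_experiment(pot$plants, pot$fertilizers, sm, run_config())
  r <- part$results
  # mass balance holds for every record, near machine precision
  expect_lt(max(abs(r$pdf_fertilizer + r$pdf_soil + r$pdf_seed - r$uptake)),
            1e-10)
  # every pot's fertilizer share equals the generating truth
  tr <- pot$truth$treatments
  share <- tr$fert_share[match(r$treatment, tr$treatment)] * 100
  expect_equal(r$pdf_fertilizer_pct, share, tolerance = 1e-9)
  # direct and indirect mineral controls agree where truth shares agree
  minp <- r[r$treatment == "MinP", ]
  expect_equal(minp$pdf_fertilizer / minp$uptake,
               rep(tr$fert_share[tr$treatment == "MinP"], nrow(minp)),
               tolerance = 1e-9)
})

test_that("direct and indirect routes agree on one consistent mixing model", {
  # same truth share for the direct and indirect mineral control
  truth <- default_pot_truth()
  truth$treatments$fert_share[truth$treatments$treatment == "MinPdir"] <- 0.42
  truth$treatments$uptake_mean_unlimed[
    truth$treatments$treatment == "MinPdir"] <- 10.0
  truth$treatments$uptake_mean_limed[
    truth$treatments$treatment == "MinPdir"] <- 10.6
  pot <- simulate_pot_experiment(truth, noise_cv_p = 0,
                                 noise_cv_activity = 0, biological_cv = 0)
  part <- partition_experiment(pot$plants, pot$fertilizers,
                               seed_p_model(truth$seed_a, truth$seed_b),
                               run_config())
  r <- part$results
  for (s in c("unlimed", "limed")) {
    direct <- r$pdf_fertilizer[r$treatment == "MinPdir" & r$soil == s]
    indirect <- r$pdf_fertilizer[r$treatment == "MinP" & r$soil == s]
    expect_equal(direct / r$uptake[r$treatment == "MinPdir" & r$soil == s],
                 indirect / r$uptake[r$treatment == "MinP" & r$soil == s],
                 tolerance = 1e-9)
  }
})

test_that("summaries: RAE of the reference treatment is 100, flags excluded", {
  pot <- simulate_pot_experiment(seed = 5L)
  sm <- seed_p_model(pot$truth$seed_a, pot$truth$seed_b)
  part <- partition_experiment(pot$plants, pot$fertilizers, sm, run_config())
  s <- part$summary
  expect_equal(s$rae_pct_mean[s$treatment == "MinP"], c(100, 100),
               tolerance = 1e-9)
  # a pot with impossible negative fertilizer P is flagged and excluded
  pot$plants$activity_bq[pot$plants$treatment == "Manure"][1] <-
    pot$plants$activity_bq[pot$plants$treatment == "NoP"][1] * 3
  part2 <- partition_experiment(pot$plants, pot$fertilizers, sm,
                                run_config(exclude_flagged = TRUE))
  flagged <- grepl("NEGATIVE_PDF_FERTILIZER", part2$results$flags)
  expect_true(any(flagged))
  man <- part2$summary[part2$summary$treatment == "Manure", ]
  expect_true(any(man$n < 4))
  # with exclude_flagged = FALSE all replicates are kept
  part3 <- partition_experiment(pot$plants, pot$fertilizers, sm,
                                run_config(exclude_flagged = FALSE))
  expect_true(all(part3$summary$n == 4))
})

test_that("predicted seed share stays in the published range over pot uptakes", {
  # the packaged synthetic calibration reproduces a seed contribution of
  # 0.65-0.95 mg P per pot, 8.6-10.7% of uptake, across the pot range
  m <- seed_p_model(0.06, 0.28)
  u <- seq(6.1, 11.0, by = 0.1)
  p <- as.numeric(predict_seed_p(u, m))
  expect_true(all(p >= 0.6 & p <= 1.0))
  expect_true(all(p / u >= 0.08 & p / u <= 0.115))
})
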