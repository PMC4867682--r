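test_that("forward model: identities, limits, and a frozen oracle value", {
  # t = 0: the power term is exactly 1, value is 1 + floor
  floor_ <- 10 * 0.09 / 568
  expect_equal(predict_r_ratio(0, 0.27, 0.40, 0.09, 568), 1 + floor_,
               tolerance = 1e-9)
  # long-time limit approaches the floor
  expect_lt(abs(predict_r_ratio(1e15, 0.27, 0.40, 0.09, 568) - floor_),
            1e-6)
  # frozen from an arbitrary-precision evaluation of the model
  expect_equal(predict_r_ratio(1, 0.27, 0.40, 0.09, 568),
               0.2675987651811416, tolerance = 1e-12)
  expect_equal(predict_r_ratio(1, 0.27, 0.40, 0.09, 568),
               oracle_r_ratio(1, 0.27, 0.40, 0.09, 568), tolerance = 1e-12)
  # strictly decreasing in t
  t <- seq(0, 90, by = 0.5)
  v <- predict_r_ratio(t, 0.3, 0.4, 0.1, 598)
  expect_true(all(diff(v) < 0))
  expect_error(predict_r_ratio(1, 0, 0.4, 0.1, 598), "m")
  expect_error(predict_r_ratio(1, 0.3, 1, 0.1, 598), "n")
})

test_that("E-value arithmetic and bounds", {
  expect_equal(e_value_1min(0.09, 100, 100), 0.9)  # r1 = R boundary
  expect_error(e_value_1min(0.09, 100, 0), "r1")
  expect_error(e_value_1min(0.09, 100, 101), "exceeds")
  # composing the forward model at t = 1 with the E-value reproduces the
  # unfertilized rows of the published incubation table within rounding
  e_unlimed <- e_value_1min(0.09, 1, predict_r_ratio(1, 0.27, 0.40, 0.09, 568))
  e_limed <- e_value_1min(0.08, 1, predict_r_ratio(1, 0.23, 0.37, 0.08, 568))
  expect_equal(e_unlimed, 3.3632, tolerance = 1e-4)
  expect_equal(e_limed, 3.4809, tolerance = 1e-4)
  e_minp <- e_value_1min(0.15, 1, predict_r_ratio(1, 0.32, 0.38, 0.15, 598))
  expect_equal(e_minp, 4.737, tolerance = 1e-3)
})

test_that("noiseless fitting recovers (m, n) on a grid to 1e-6", {
  for (m in c(0.1, 0.2, 0.3)) for (n in c(0.2, 0.35, 0.5)) {
    ser <- simulate_kinetics_series(m, n, 0.1, 598, noise_cv = 0)
    ft <- fit_kinetics(ser)
    expect_lt(abs(ft$m - m), 1e-6)
    expect_lt(abs(ft$n - n), 1e-6)
    expect_true(ft$converged)
    # model passes through the data: fitted and raw E-values coincide
    expect_equal(e_value_from_fit(ft, ser, "fitted"),
                 e_value_from_fit(ft, ser, "raw"), tolerance = 1e-6)
  }
})

test_that("E1min from fits respects its physical bounds", {
  set.seed(3)
  for (i in 1:20) {
    m <- runif(1, 0.1, 0.6); n <- runif(1, 0.2, 0.6)
    c_p <- runif(1, 0.05, 0.3); pi_total <- runif(1, 400, 700)
    ser <- simulate_kinetics_series(m, n, c_p, pi_total, noise_cv = 0.02)
    ft <- fit_kinetics(ser)
    expect_gte(ft$e1min, 10 * c_p)
    expect_lte(ft$e1min, pi_total)
  }
})

test_that("noisy fitting is centred on the truth", {
  set.seed(99)
  ms <- replicate(200, {
    ser <- simulate_kinetics_series(0.30, 0.40, 0.12, 598, noise_cv = 0.02)
    fit_kinetics(ser)$m
  })
  expect_lt(abs(stats::median(ms) - 0.30), 0.02)
})

test_that("degenerate and invalid series are rejected", {
  expect_error(kinetics_series(c(1, 4, 2), c(3, 2, 1), 10, 0.1, 598),
               "increasing")
  expect_error(kinetics_series(c(1, 4, 10), c(3, 2, 11), 10, 0.1, 598),
               "r_t")
  ser <- kinetics_series(c(1, 4, 10, 30), rep(5, 4), 10, 0.1, 598)
  expect_error(fit_kinetics(ser), "degenerate")
  expect_warning(kinetics_series(c(1, 4, 10), c(3, 2, 2.9), 10, 0.1, 598),
                 "tolerance")
})

test_that("published incubation rows are internally consistent", {
  # recomputing E1min from each row's printed (C_P, m, n) and the soil
  # inorganic-P basis agrees with the printed E1min within two-decimal
  # input rounding (+/- 0.25)
  inc <- reference_tables()$incubation
  cfg <- run_config()
  pi_base <- cfg$soil_total_p - cfg$soil_organic_p
  for (i in seq_len(nrow(inc))) {
    pi_total <- pi_base + if (inc$treatment[i] == "NoP") 0 else 30
    e <- e_value_1min(inc$c_p_mg_per_l[i], 1,
                      predict_r_ratio(1, inc$m[i], inc$n[i],
                                      inc$c_p_mg_per_l[i], pi_total))
    expect_lt(abs(e - inc$e1min_mg_per_kg[i]), 0.25)
  }
})
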