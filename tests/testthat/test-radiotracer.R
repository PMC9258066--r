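mk_series <- function(times, y, sa = 10, dm = 0.05, adm = 1000, meoh = 0) {
  trap_series(times, y, methanol_trap_activity = meoh,
              administered_activity = adm, dry_mass = dm,
              specific_activity = sa)
}

test_that("slope fitting recovers exact lines and flat series", {
  fit <- fit_turnover_slope(mk_series(c(0, 0.5, 1), c(0, 50, 100)))
  expect_equal(fit$slope, 100)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)

  flat <- fit_turnover_slope(mk_series(c(0, 1, 2), c(10, 10, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)  # collinear points

  expect_error(mk_series(c(1, 1), c(0, 5)), "strictly increasing")
  expect_error(mk_series(1, 5), "at least 2 timepoints")
})

test_that("noisy slope estimates are unbiased", {
  set.seed(13)
  times <- seq(0.5, 4, by = 0.5)
  slopes <- replicate(500, {
    y <- pmax(80 * times + rnorm(8, 0, 2), 0)
    fit_turnover_slope(mk_series(times, cummax(y)))$slope
  })
  expect_lt(abs(mean(slopes) / 80 - 1), 0.01)
})

test_that("rate conversion follows the unit arithmetic and scaling laws", {
  s <- mk_series(c(0, 1), c(0, 100), sa = 10, dm = 0.05)
  expect_equal(consumption_rate(100, s)$rate, 200)
  expect_equal(consumption_rate(0, s)$rate, 0)
  # doubling dry mass halves the rate; same for specific activity
  set.seed(21)
  for (i in 1:20) {
    sl <- runif(1, 1, 500); sa <- runif(1, 1, 50); dm <- runif(1, 0.01, 0.2)
    r1 <- consumption_rate(sl, mk_series(c(0, 1), c(0, 1), sa, dm))$rate
    r2 <- consumption_rate(sl, mk_series(c(0, 1), c(0, 1), sa, 2 * dm))$rate
    r3 <- consumption_rate(2 * sl, mk_series(c(0, 1), c(0, 1), sa, dm))$rate
    expect_equal(r2, r1 / 2)
    expect_equal(r3, 2 * r1)
  }
  # negative slope clamps to zero with a warning and keeps the raw slope
  expect_warning(out <- consumption_rate(-5, s), "clamped")
  expect_equal(out$rate, 0)
  expect_equal(out$slope, -5)
  expect_true(out$clamped)
})

test_that("specific activity is a mandatory input", {
  expect_error(trap_series(c(0, 1), c(0, 10), 0, 1000, 0.05, NULL),
               "configuration error.*specific_activity")
  expect_error(trap_series(c(0, 1), c(0, 10), 0, 1000, 0.05, -1),
               "specific_activity")
})

test_that("mass balance divides recoveries out of the administered activity", {
  s <- mk_series(c(0, 1), c(0, 100), adm = 1000, meoh = 875)
  mb <- mass_balance(s)
  expect_equal(mb$co2_recovery, 0.10)
  expect_equal(mb$methanol_recovery, 0.875)
  expect_equal(mb$total_recovery, 0.975)
  expect_false(mb$qc_flag)
  expect_equal(mass_balance(mk_series(c(0, 1), c(0, 5), meoh = 0))$methanol_recovery, 0)
  # recovery above 1 flags but does not abort
  expect_warning(mb2 <- mass_balance(mk_series(c(0, 1), c(0, 600), adm = 1000,
                                               meoh = 600)),
                 "QC")
  expect_true(mb2$qc_flag)
})

test_that("NaOH/BaCO3 cross-check reproduces forced cases and matches Pearson", {
  v <- c(12, 40, 7, 55, 23)
  same <- cross_check(v, v)
  expect_equal(same$percent_excess, 0)
  expect_equal(same$r_squared, 1)

  scaled <- cross_check(v, 1.033 * v)
  expect_equal(scaled$percent_excess, 3.3)
  expect_equal(scaled$r_squared, 1)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    naoh <- runif(n, 10, 100)
    baco3 <- naoh + rnorm(n, 0, 10)
    out <- cross_check(naoh, baco3)
    expect_equal(out$r_squared, cor(naoh, baco3)^2, tolerance = 1e-10)
  }
  expect_error(cross_check(c(0, 0), c(1, 2)), "zero")
})

test_that("R-squared is invariant under affine rescaling of both axes", {
  set.seed(41)
  naoh <- runif(10, 5, 50)
  baco3 <- 1.1 * naoh + rnorm(10, 0, 4)
  base <- cross_check(naoh, baco3)$r_squared
  resc <- cross_check(3.7 * naoh + 11, 0.2 * baco3 - 5)$r_squared
  expect_equal(resc, base, tolerance = 1e-10)
})

test_that("interval collections convert to cumulative by running sum", {
  expect_equal(intervals_to_cumulative(c(5, 3, 2)), c(5, 8, 10))
  expect_error(intervals_to_cumulative(c(5, -1)), "non-negative")
})

test_that("the classed turnover fit exposes coef/predict/residuals", {
  sim <- simulate_trap_series(trap_sim_params(true_rate = 50, noise_sd = 0,
                                              trap_efficiency = 1, seed = 2))
  fit <- fit_turnover(sim$series)
  expect_s3_class(fit, "turnover_fit")
  expect_equal(fit$rate, 50, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["slope"]), fit$slope)
  expect_equal(predict(fit), fit$series$co2_activity, tolerance = 1e-8)
  expect_equal(residuals(fit), rep(0, length(fit$series$times)),
               tolerance = 1e-8)
  expect_output(print(fit), "Methanol turnover fit")
})
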