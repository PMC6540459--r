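test_that("retention fraction matches the closed form and its limits", {
  expect_equal(retention_fraction(0), 1.0)
  # closed-form evaluation at day 5: 0.20 exp(-0.693*5/0.6) + 0.80 exp(-0.693*5/7.8)
  expect_equal(retention_fraction(5), 0.5136748, tolerance = 1e-6)
  # about half the injected activity is excreted by day 5
  expect_lt(abs((1 - retention_fraction(5)) - 0.5), 0.02)
  expect_lt(retention_fraction(1000), 1e-30)
  # strictly decreasing and within (0, 1]
  grid <- seq(0, 30, by = 0.25)
  vals <- retention_fraction(grid)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  expect_error(retention_fraction(-1), "must be finite")
})

test_that("cumulative disintegrations agree with quadrature and scale linearly", {
  # closed-form long-time limit for 1 Bq: 86400 * sum_i f_i T_i / 0.693
  expect_equal(
    cumulative_disintegrations(1, 1e4),
    86400 * (0.2 * 0.6 + 0.8 * 7.8) / 0.693,
    tolerance = 1e-12
  )
  expect_equal(cumulative_disintegrations(5, 0), 0)
  # oracle equivalence: numerical quadrature of activity x retention x 86400
  params_list <- list(
    retention_params(),
    retention_params(0.35, 0.3, 0.65, 5),
    retention_params(0.05, 1.2, 0.95, 12)
  )
  for (p in params_list) {
    for (t in c(0.5, 2, 5, 14)) {
      quad <- stats::integrate(
        function(s) retention_fraction(s, p), 0, t,
        rel.tol = 1e-12
      )$value * 86400
      expect_equal(cumulative_disintegrations(1, t, p), quad, tolerance = 1e-8)
    }
  }
  # linear in activity
  t <- c(1, 3, 7)
  expect_equal(
    cumulative_disintegrations(4e6, t),
    2 * cumulative_disintegrations(2e6, t)
  )
  expect_error(cumulative_disintegrations(-1, 2), "must be finite")
})

test_that("dose coefficient and committed dose behave as products", {
  expect_equal(dose_coefficient(0), 0)
  expect_gte(dose_coefficient(14), dose_coefficient(5))
  # closed form against the disintegration count
  expect_equal(
    dose_coefficient(14, see = 2.41e-19),
    cumulative_disintegrations(1, 14) * 2.41e-19
  )
  expect_equal(committed_dose(0, 1e-12), 0)
  expect_equal(committed_dose(3e6, 0), 0)
  expect_equal(committed_dose(2 * 3e6, 1e-12), 2 * committed_dose(3e6, 1e-12))
})

test_that("daily dose rates telescope and decrease for the default kinetics", {
  days <- 0:14
  doses <- committed_dose(5.74e6, dose_coefficient(days))
  rates <- daily_dose_rate(doses)
  expect_equal(sum(rates$dose_rate_gy_per_day), doses[length(doses)])
  expect_true(all(diff(rates$dose_rate_gy_per_day) < 0))
  expect_true(all(rates$dose_rate_gy_per_day >= 0))
  expect_warning(daily_dose_rate(c(0, 2, 1)), "not monotone")
  # plateaued series has zero rates
  expect_equal(daily_dose_rate(c(1, 1, 1))$dose_rate_gy_per_day, c(0, 0))
})

test_that("dose_table reports doses and rates on the requested grid", {
  tab <- dose_table(c(5.74, 9.28), days = c(2, 3, 5, 7, 14))
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$committed_dose_gy > 0))
  expect_true(all(tab$dose_rate_gy_per_day > 0))
  # dose increases with day within each activity
  by_act <- split(tab, tab$activity_mbq)
  for (g in by_act) expect_true(all(diff(g$committed_dose_gy) > 0))
  # calibration reproduces an anchor dose exactly
  see_cal <- calibrate_see(5.74, 5, 2.42)
  d <- committed_dose(5.74e6, dose_coefficient(5, see = see_cal))
  expect_equal(d, 2.42, tolerance = 1e-12)
})

test_that("retention fitting recovers generating parameters", {
  days <- 0:14
  p0 <- retention_params()
  clean <- tibble::tibble(day = days, fraction_retained = retention_fraction(days, p0))
  fit <- fit_retention(clean, n_terms = 2)
  expect_true(fit$converged)
  expect_equal(fit$params$fraction_fast, 0.20, tolerance = 1e-4)
  expect_equal(fit$params$halftime_fast, 0.6, tolerance = 1e-4)
  expect_equal(fit$params$halftime_slow, 7.8, tolerance = 1e-4)

  # single-exponential series fitted with one term
  single <- tibble::tibble(
    day = days,
    fraction_retained = exp(-0.693 * days / 7.8)
  )
  fit1 <- fit_retention(single, n_terms = 1)
  expect_equal(fit1$params$halftime_slow, 7.8, tolerance = 1e-4)
  expect_equal(fit1$params$fraction_fast, 0)

  expect_error(fit_retention(clean[1:3, ], n_terms = 2), "at least 5 points")
})

test_that("retention fitting tolerates measurement noise", {
  p0 <- retention_params()
  days <- c(1:7, 10, 14)
  slow_rec <- withr::with_seed(42, {
    vapply(1:20, function(i) {
      y <- pmin(pmax(
        retention_fraction(days, p0) + rnorm(length(days), 0, 0.02),
        1e-3
      ), 1.2)
      fit_retention(
        tibble::tibble(day = days, fraction_retained = y),
        seed = i
      )$params$halftime_slow
    }, numeric(1))
  })
  expect_lt(abs(median(slow_rec) / 7.8 - 1), 0.15)
})
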