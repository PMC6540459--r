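test_that("activity inversion round-trips exact forward values", {
  Fv <- predict_fluorescence(truth, 5.74, 2)
  res <- estimate_activity(truth, 2, Fv, branch = "high")
  expect_equal(res$estimate, 5.74, tolerance = 1e-4)
  expect_identical(res$flag, "ok")

  # background-level fluorescence falls below the model's range on the branch
  res_bg <- estimate_activity(truth, 2, truth$b, branch = "high")
  expect_identical(res_bg$flag, "out_of_range")
  expect_equal(res_bg$estimate, 20)

  # fluorescence above the response ceiling saturates at 1/alpha
  f_max <- predict_fluorescence(truth, activity_of_max_response(truth), 2)
  res_sat <- estimate_activity(truth, 2, f_max + 100, branch = "high")
  expect_identical(res_sat$flag, "saturated")
  expect_equal(res_sat$estimate, activity_of_max_response(truth))
})

test_that("the low branch finds the conjugate root", {
  Fv <- predict_fluorescence(truth, 5.74, 2)
  lo <- estimate_activity(truth, 2, Fv, branch = "low")
  expect_identical(lo$flag, "ok")
  expect_lt(lo$estimate, activity_of_max_response(truth))
  # dense-grid brute force over A in (0, 20], step 1e-3
  grid <- seq(1e-3, 20, by = 1e-3)
  fvals <- (predict_fluorescence(truth, grid, 2) - Fv)^2
  low_side <- grid < activity_of_max_response(truth)
  oracle <- grid[low_side][which.min(fvals[low_side])]
  expect_equal(lo$estimate, oracle, tolerance = 2e-3)
  # both roots reproduce the measured fluorescence
  expect_equal(predict_fluorescence(truth, lo$estimate, 2), Fv, tolerance = 1e-4)
  # global branch prefers the better root, ties toward "high"
  glob <- estimate_activity(truth, 2, Fv, branch = "global")
  expect_equal(glob$estimate, 5.74, tolerance = 1e-3)
})

test_that("estimates decrease with fluorescence on the high branch", {
  f_grid <- seq(1100, 1300, by = 20)
  est <- vapply(f_grid, function(f) {
    estimate_activity(truth, 2, f, branch = "high")$estimate
  }, numeric(1))
  expect_true(all(diff(est) < 0))
})

test_that("confidence-region sampling is reproducible and respects the region", {
  fit <- noisefree_fit()
  ens <- sample_confidence_region(fit, n_min = 200, seed = 9)
  expect_equal(ens$n_draws, 200)
  # every accepted draw re-checks as a region member
  ok <- vapply(seq_len(ens$n_draws), function(i) {
    in_confidence_region(as_params(ens$draws[i, ]), fit)
  }, logical(1))
  expect_true(all(ok))
  # reproducibility
  ens2 <- sample_confidence_region(fit, n_min = 200, seed = 9)
  expect_equal(ens$draws, ens2$draws)
  # vanishing proposal scale accepts (almost) everything near the best fit
  tight <- sample_confidence_region(fit, n_min = 50, seed = 1, scale = rep(1e-8, 4))
  expect_gt(tight$acceptance_rate, 0.999)
  expect_equal(tight$draws$alpha, rep(fit$params$alpha, 50), tolerance = 1e-6)
})

test_that("summaries aggregate per-draw estimates and flag undefined points", {
  fit <- noisefree_fit()
  # near-degenerate ensemble: medians reproduce the true activities
  tight <- sample_confidence_region(fit, n_min = 5, seed = 1, scale = rep(1e-8, 4))
  pts <- dplyr::filter(noisefree_means, .data$activity_mbq > 0) |>
    dplyr::transmute(day, mean_fluorescence,
      true_activity_mbq = .data$activity_mbq)
  est <- summarize_estimates(tight, pts, branch = "high")
  expect_equal(est$median_activity, pts$true_activity_mbq, tolerance = 1e-3)
  expect_true(all(est$min_activity <= est$median_activity))
  expect_true(all(est$median_activity <= est$max_activity))
  # single-draw ensemble collapses the range
  single <- sample_confidence_region(fit, n_min = 1, seed = 2, scale = rep(1e-8, 4))
  est1 <- summarize_estimates(single, pts[1, ])
  expect_equal(est1$min_activity, est1$median_activity)
  expect_equal(est1$max_activity, est1$median_activity)
  # a fluorescence no draw can reach is undefined, not silently numeric
  bad <- tibble::tibble(day = 2, mean_fluorescence = 10 * truth$b)
  est_bad <- summarize_estimates(tight, bad)
  expect_true(est_bad$undefined)
  expect_true(is.na(est_bad$median_activity))
  expect_equal(est_bad$n_flagged, 5)
})

test_that("widening the confidence level never shrinks the region", {
  fit <- noisefree_fit()
  ens95 <- sample_confidence_region(fit, n_min = 100, seed = 4)
  # every 95% member is a 99% member (nested deviance thresholds)
  ok99 <- vapply(seq_len(ens95$n_draws), function(i) {
    in_confidence_region(as_params(ens95$draws[i, ]), fit, level = 0.99)
  }, logical(1))
  expect_true(all(ok99))
})

test_that("correlation reports match hand-computed statistics", {
  mk_est <- function(x, y) {
    tibble::tibble(
      day = rep(2, length(x)), median_activity = y,
      true_activity_mbq = x, undefined = FALSE
    )
  }
  perfect <- correlation_report(mk_est(1:4, 1:4), list(c(2, 2)))
  expect_equal(perfect$spearman_rho, 1.0)
  anti <- correlation_report(mk_est(1:4, 4:1), list(c(2, 2)))
  expect_equal(anti$spearman_rho, -1.0)

  # eight-pair Pearson oracle computed from the centred-sum formula
  x <- 1:8
  y <- c(1.1, 1.9, 3.2, 3.8, 5.3, 5.7, 7.2, 7.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((8 - 2) / (1 - r_hand^2))
  p_hand <- 2 * stats::pt(-abs(t_hand), df = 6)
  rep8 <- correlation_report(mk_est(x, y), list(c(2, 2)))
  expect_equal(rep8$pearson_r, r_hand, tolerance = 1e-12)
  expect_equal(rep8$pearson_p, p_hand, tolerance = 1e-12)

  # degenerate inputs are flagged, not fabricated
  flat <- correlation_report(mk_est(1:4, rep(2, 4)), list(c(2, 2)))
  expect_true(flat$flagged)
  expect_true(is.na(flat$pearson_r))
})

test_that("activity-to-dose conversion uses the measured coefficient grid", {
  coeffs <- dose_coefficients()
  # day-2 coefficient is the mean of the four measured dose/activity ratios
  expect_equal(
    coeffs$gy_per_mbq[coeffs$day == 2],
    mean(c(1.31 / 5.74, 1.62 / 6.66, 2.16 / 7.65, 2.98 / 9.28))
  )
  expect_gt(
    coeffs$gy_per_mbq[coeffs$day == 14],
    coeffs$gy_per_mbq[coeffs$day == 2]
  )
  expect_equal(activity_to_dose(0, 2), 0)
  expect_error(activity_to_dose(5, 4), "outside the coefficient grid")
  expect_warning(d4 <- activity_to_dose(5, 4, interpolate = TRUE), "Interpolating")
  d3 <- activity_to_dose(5, 3)
  d5 <- activity_to_dose(5, 5)
  expect_true(d4 > d3 && d4 < d5)
})
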