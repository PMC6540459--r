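test_that("the weighted Gaussian likelihood has its textbook form", {
  data <- noisefree_means
  # zero residuals leave only the normalisation terms
  expect_equal(
    h2ax_nll(truth, data),
    sum(log(data$sem)) + nrow(data) / 2 * log(2 * pi)
  )
  # doubling all sems: residual term scales by 1/4, normalisation adds log 2 each
  noisy <- data
  noisy$mean_fluorescence <- noisy$mean_fluorescence + 10
  resid_term <- function(d) h2ax_nll(truth, d) - sum(log(d$sem)) - nrow(d) / 2 * log(2 * pi)
  doubled <- noisy
  doubled$sem <- 2 * doubled$sem
  expect_equal(resid_term(doubled), resid_term(noisy) / 4)
  # non-finite predictions are optimizer-safe
  expect_error(h2ax_nll(truth, dplyr::mutate(data, sem = 0)), "positive")
})

test_that("the generating parameters dominate seeded perturbations in likelihood", {
  nll0 <- h2ax_nll(truth, noisefree_means)
  worse <- withr::with_seed(7, {
    vapply(1:100, function(i) {
      pert <- h2ax_params(
        k = truth$k * runif(1, 0.8, 1.2),
        alpha = truth$alpha * runif(1, 0.8, 1.2),
        r = truth$r * runif(1, 0.8, 1.2),
        p = truth$p * runif(1, 0.8, 1.2),
        b = truth$b
      )
      h2ax_nll(pert, noisefree_means)
    }, numeric(1))
  })
  expect_true(all(worse >= nll0))
})

test_that("fitting zero-noise data recovers the generating kinetics", {
  fit <- noisefree_fit()
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k / truth$k - 1), 0.01)
  expect_lt(abs(fit$params$alpha / truth$alpha - 1), 0.01)
  expect_lt(abs(fit$params$r / truth$r - 1), 0.01)
  expect_lt(abs(fit$params$p / truth$p - 1), 0.01)
  # reported weighted SSR is internally consistent
  pred <- predict_fluorescence(fit$params, fit$data$activity_mbq, fit$data$day)
  expect_equal(
    fit$weighted_ssr,
    sum((fit$data$mean_fluorescence - pred)^2 / fit$data$sem^2)
  )
  # the optimum is no worse than the deterministic centre start
  mid <- h2ax_params(k = sqrt(1e4 * 1e7), alpha = sqrt(0.02 * 2),
    r = sqrt(1e4 * 1e8), p = sqrt(0.05 * 0.8), b = 1006)
  expect_lte(fit$nll, h2ax_nll(mid, fit$data))
})

test_that("fits are invariant to row order", {
  gm <- generate_group_means(design5, truth, noise_config(), seed = 11)
  f1 <- fit_h2ax(gm, n_starts = 6, seed = 2)
  f2 <- fit_h2ax(gm[sample(nrow(gm)), ], n_starts = 6, seed = 2)
  expect_equal(f1$nll, f2$nll, tolerance = 1e-6)
  expect_equal(unlist(f1$params), unlist(f2$params), tolerance = 1e-6)
})

test_that("single-activity designs are reported as non-identifiable", {
  one_act <- generate_group_means(
    study_design(activities = 5.74, include_control = FALSE),
    truth, noise_config(), seed = 3
  )
  expect_warning(
    fit <- fit_h2ax(one_act, n_starts = 4, seed = 1),
    "not jointly identifiable"
  )
  expect_false(fit$identifiable)
})

test_that("profile intervals bracket the estimate and flag open ends", {
  fit <- noisefree_fit()
  ci <- profile_ci(fit, "alpha")
  expect_lte(ci$conf.low, ci$estimate)
  expect_gte(ci$conf.high, ci$estimate)
  expect_false(ci$low_open)
  expect_false(ci$high_open)
  # zero-noise data generated at the defaults: interval should cover them
  expect_lt(ci$conf.low, truth$alpha)
  expect_gt(ci$conf.high, truth$alpha)
  expect_error(profile_ci(fit, "bogus"), "must be one of")
})

test_that("confidence-region membership matches the deviance rule", {
  fit <- noisefree_fit()
  expect_true(in_confidence_region(fit$params, fit))
  # a hopeless candidate is rejected
  far <- h2ax_params(k = 1e4, alpha = 2, r = 1e4, p = 0.79, b = 1006)
  expect_false(in_confidence_region(far, fit))
  # oracle equivalence on a list of seeded proposals
  threshold <- qchisq(0.95, df = 4)
  props <- withr::with_seed(5, {
    lapply(1:50, function(i) {
      h2ax_params(
        k = truth$k * exp(rnorm(1, 0, 0.3)),
        alpha = truth$alpha * exp(rnorm(1, 0, 0.3)),
        r = truth$r * exp(rnorm(1, 0, 0.3)),
        p = plogis(qlogis(truth$p) + rnorm(1, 0, 0.3)),
        b = truth$b
      )
    })
  })
  member <- vapply(props, in_confidence_region, logical(1), fit = fit)
  oracle <- vapply(props, function(pp) {
    2 * (h2ax_nll(pp, fit$data) - fit$nll) <= threshold
  }, logical(1))
  expect_identical(member, oracle)
  expect_gt(mean(member), 0) # the proposal cloud straddles the boundary
  expect_lt(mean(member), 1)
})
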