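test_that("group-mean generation is exact at zero noise and seeded otherwise", {
  gm0 <- generate_group_means(design5, truth, noise_config(group_sem = 0), seed = 1)
  expect_equal(
    gm0$mean_fluorescence,
    predict_fluorescence(truth, gm0$activity_mbq, gm0$day)
  )
  expect_true(all(gm0$sem > 0))
  expect_equal(gm0$n, design5$n_animals)

  a <- generate_group_means(design5, truth, noise_config(), seed = 2)
  b <- generate_group_means(design5, truth, noise_config(), seed = 2)
  c <- generate_group_means(design5, truth, noise_config(), seed = 3)
  expect_equal(a, b)
  expect_false(isTRUE(all.equal(a$mean_fluorescence, c$mean_fluorescence)))
})

test_that("group-mean noise calibrates to the target SEM", {
  one_point <- study_design(activities = 5.74, days = 2, include_control = FALSE)
  means <- vapply(1:500, function(i) {
    generate_group_means(one_point, truth, noise_config(), seed = i)$mean_fluorescence
  }, numeric(1))
  expect_lt(abs(sd(means) / 36 - 1), 0.10)
})

test_that("retention curves express inter-animal variability around the population", {
  rc0 <- generate_retention_curves(design5, cv = 0, seed = 1)
  pop <- retention_fraction(rc0$day)
  expect_equal(rc0$fraction_retained, pop)
  # counting schedule: daily for a week, then days 10 and 14
  expect_equal(sort(unique(rc0$day)), c(1:7, 10, 14))

  rc <- generate_retention_curves(design5, cv = 0.15, seed = 1)
  day5 <- rc$fraction_retained[rc$day == 5]
  expect_gt(length(day5), 8)
  expect_lt(abs(mean(day5) - 0.5137), 0.02)
  # per-animal truth is recoverable by the retention fitter at cv = 0
  one <- dplyr::filter(rc0, .data$animal_id == rc0$animal_id[1])
  refit <- fit_retention(one[, c("day", "fraction_retained")])
  expect_equal(refit$params$halftime_slow, 7.8, tolerance = 1e-3)
})

test_that("per-cell samples hit their post-filter target mean", {
  noise <- noise_config()
  cs <- generate_cells(1200, n_cells = 1e5, noise = noise, seed = 8)
  kept <- cs$fluorescence[cs$fluorescence <= 3000]
  expect_lt(abs(mean(kept) / 1200 - 1), 0.02)
  # the apoptotic tail is the only mass above the cutoff
  expect_lt(abs(mean(cs$fluorescence > 3000) - noise$tail_weight), 0.01)
  expect_true(all(cs$fluorescence[cs$fluorescence <= 3000] > 0))
  # no tail, no filtering losses
  cs0 <- generate_cells(800, 5000, noise_config(tail_weight = 0), seed = 3)
  expect_equal(attr(filter_high_fluorescence(
    tibble::tibble(fluorescence = cs0$fluorescence)
  ), "n_removed"), 0)
  # determinism
  expect_equal(
    generate_cells(900, 100, seed = 4),
    generate_cells(900, 100, seed = 4)
  )
  expect_error(generate_cells(2950, 100), "unattainable")
})

test_that("full-study bundles are self-consistent end to end", {
  bundle <- generate_full_study(
    design5, truth, noise = noise_config(group_sem = 0), seed = 1
  )
  fit <- fit_h2ax(bundle$group_means, n_starts = 8, seed = 1)
  expect_lt(abs(fit$params$k / truth$k - 1), 0.01)
  expect_lt(abs(fit$params$alpha / truth$alpha - 1), 0.01)
  expect_lt(abs(fit$params$r / truth$r - 1), 0.01)
  expect_lt(abs(fit$params$p / truth$p - 1), 0.01)

  # cell-level aggregation reproduces the group table within Monte-Carlo error
  small <- study_design(
    activities = c(5.74, 9.28), days = c(2, 5), animals_per_point = 4,
    include_control = FALSE
  )
  wb <- generate_full_study(small, truth, noise = noise_config(), seed = 2, cells = TRUE)
  agg <- group_summary(wb$cells)
  merged <- dplyr::inner_join(
    agg, wb$group_means,
    by = c("activity_mbq", "day"), suffix = c("_cells", "_groups")
  )
  expect_equal(nrow(merged), 4)
  expect_true(all(
    abs(merged$mean_fluorescence_cells / merged$mean_fluorescence_groups - 1) < 0.05
  ))
})

test_that("bundle CSV output is byte-identical under the same seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  small <- study_design(activities = 5.74, days = c(2, 5), animals_per_point = 2)
  generate_full_study(small, truth, noise = noise_config(), seed = 11, out_dir = d1)
  generate_full_study(small, truth, noise = noise_config(), seed = 11, out_dir = d2)
  for (f in c("group_means.csv", "retention.csv", "manifest.json")) {
    expect_identical(
      readLines(file.path(d1, f)),
      readLines(file.path(d2, f))
    )
  }
})

test_that("the generator spans the study's dose and dose-rate contrasts", {
  # similar dose rate, different dose / similar dose, different dose rate:
  # computable from the biokinetics grid on generated activities
  tab <- dose_table(c(5.74, 6.66, 7.65, 9.28), days = c(2, 3, 5, 7, 14))
  # a fixed-day slice has increasing dose with activity
  day2 <- dplyr::filter(tab, .data$day == 2)
  expect_true(all(diff(day2$committed_dose_gy) > 0))
  # the same committed dose is reached by different activities at different
  # times, with different instantaneous dose rates
  lo_late <- dplyr::filter(tab, .data$activity_mbq == 5.74, .data$day == 7)
  hi_early <- dplyr::filter(tab, .data$activity_mbq == 9.28, .data$day == 3)
  ratio <- hi_early$committed_dose_gy / lo_late$committed_dose_gy
  expect_lt(abs(ratio - 1), 0.35)
  expect_gt(hi_early$dose_rate_gy_per_day, lo_late$dose_rate_gy_per_day)
})
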