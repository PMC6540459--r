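# Seeded synthetic-study generator. Reproduces the design of the mouse
# internal-emitter study (four activities plus vehicle control, five
# necropsy days, eight animals per data point, 150-500 scored cells per
# sample) with the statistical structure the downstream analysis assumes:
# Gaussian group-level noise around the kinetic model, biexponential
# retention with log-normal inter-animal variability in the half-times, and
# a per-cell log-normal bulk plus an apoptotic high-fluorescence tail.

#' Study design grid
#'
#' One row per (activity, necropsy day) data point. Defaults reproduce the
#' emulated study: activities 5.74, 6.66, 7.65 and 9.28 MBq plus a vehicle
#' control, necropsy on days 2, 3, 5, 7 and 14, eight animals per point,
#' and 150-500 scored cells per sample.
#'
#' @param activities Injected activities in MBq.
#' @param days Necropsy days.
#' @param animals_per_point Animals per (activity, day) data point.
#' @param cells_range Range of scored cells per animal sample.
#' @param include_control Add a 0-MBq vehicle-control group.
#' @return Tibble with columns `activity_mbq`, `day`, `n_animals`, and a
#'   `cells_range` attribute.
#' @export
study_design <- function(activities = c(5.74, 6.66, 7.65, 9.28),
                         days = c(2, 3, 5, 7, 14),
                         animals_per_point = 8,
                         cells_range = c(150, 500),
                         include_control = TRUE) {
  check_nonneg(activities, "activities")
  stopifnot(all(days > 0), animals_per_point >= 1, length(cells_range) == 2,
    cells_range[1] >= 1, cells_range[2] >= cells_range[1])
  if (include_control) activities <- c(0, activities)
  out <- tidyr::expand_grid(activity_mbq = sort(unique(activities)), day = sort(days))
  out$n_animals <- as.integer(animals_per_point)
  attr(out, "cells_range") <- cells_range
  out
}

#' Noise configuration for the synthetic generator
#'
#' @param group_sem Target standard error of a group mean in AU. The
#'   default 36 AU matches the observed variability of the control-group
#'   background (overall control mean 1006 +/- 36 AU).
#' @param retention_cv Fractional inter-animal coefficient of variation on
#'   the retention half-times.
#' @param cell_sdlog Log-scale SD of the per-cell bulk fluorescence
#'   distribution.
#' @param tail_weight Fraction of cells in the apoptotic high-fluorescence
#'   tail (a fixture choice; the study reports only that such cells exist
#'   and are filtered at 3000 AU).
#' @param tail_meanlog,tail_sdlog Log-normal parameters of the tail excess
#'   above 3000 AU.
#' @return List of class `noise_config`.
#' @export
noise_config <- function(group_sem = 36, retention_cv = 0.15,
                         cell_sdlog = 0.5, tail_weight = 0.05,
                         tail_meanlog = log(1500), tail_sdlog = 0.5) {
  stopifnot(group_sem >= 0, retention_cv >= 0, cell_sdlog > 0,
    tail_weight >= 0, tail_weight < 1, tail_sdlog > 0)
  structure(
    list(
      group_sem = group_sem, retention_cv = retention_cv,
      cell_sdlog = cell_sdlog, tail_weight = tail_weight,
      tail_meanlog = tail_meanlog, tail_sdlog = tail_sdlog
    ),
    class = "noise_config"
  )
}

#' Generate group-level mean fluorescence measurements
#'
#' For each design point, draws per-animal mean fluorescences from a
#' Gaussian centred on the kinetic-model prediction with SD
#' `sqrt(n) * group_sem` (so the SEM of the group mean matches the target),
#' then reports the group mean, its empirical SEM and the animal count.
#'
#' @param design A [study_design()] tibble.
#' @param truth An [h2ax_params()] object generating the data.
#' @param noise A [noise_config()]; `group_sem = 0` is allowed and yields
#'   noise-free means with `sem` set to the configured floor `sem_floor`.
#' @param seed Seed; the same seed reproduces the dataset exactly.
#' @param sem_floor SEM reported for noise-free data (weights must stay
#'   finite).
#' @return Tibble with columns `activity_mbq`, `day`, `mean_fluorescence`,
#'   `sem`, `n`.
#' @export
generate_group_means <- function(design, truth = h2ax_params(),
                                 noise = noise_config(), seed = 1,
                                 sem_floor = 36) {
  check_columns(design, c("activity_mbq", "day", "n_animals"), "design")
  withr::with_seed(child_seed(seed, 101L), {
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      a <- design$activity_mbq[i]
      d <- design$day[i]
      n <- design$n_animals[i]
      mu <- predict_fluorescence(truth, a, d)
      if (noise$group_sem > 0) {
        animal_means <- rnorm(n, mean = mu, sd = sqrt(n) * noise$group_sem)
        tibble::tibble(
          activity_mbq = a, day = d,
          mean_fluorescence = mean(animal_means),
          sem = sd(animal_means) / sqrt(n), n = n
        )
      } else {
        tibble::tibble(
          activity_mbq = a, day = d, mean_fluorescence = mu,
          sem = sem_floor, n = n
        )
      }
    })
  })
}

#' Generate per-animal whole-body retention series
#'
#' Each animal gets its own biexponential retention curve: half-times drawn
#' log-normally around the population values with coefficient of variation
#' `cv` (fractions are kept at the population values, which already sum to
#' one). Series are sampled on the counting schedule: daily for the first
#' seven days, then days 10 and 14.
#'
#' @param design A [study_design()] tibble (control rows are skipped -
#'   unexposed animals have no retention curve).
#' @param params Population [retention_params()].
#' @param cv Inter-animal CV of the half-times; `0` makes every animal
#'   identical to the population curve.
#' @param seed Seed.
#' @param days Sampling days.
#' @return Tibble with columns `animal_id`, `activity_mbq`, `day`,
#'   `fraction_retained`; per-animal true half-times are attached as
#'   attribute `"animal_params"`.
#' @export
generate_retention_curves <- function(design, params = retention_params(),
                                      cv = 0.15, seed = 1,
                                      days = c(1:7, 10, 14)) {
  check_columns(design, c("activity_mbq", "day", "n_animals"), "design")
  groups <- design |>
    dplyr::filter(.data$activity_mbq > 0) |>
    dplyr::distinct(.data$activity_mbq, .data$n_animals)
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(child_seed(seed, 211L), {
    animal_rows <- purrr::map_dfr(seq_len(nrow(groups)), function(g) {
      n <- groups$n_animals[g]
      tibble::tibble(
        activity_mbq = groups$activity_mbq[g],
        animal = seq_len(n),
        halftime_fast = params$halftime_fast *
          exp(rnorm(n, -sdlog^2 / 2, sdlog)),
        halftime_slow = params$halftime_slow *
          exp(rnorm(n, -sdlog^2 / 2, sdlog))
      )
    })
    animal_rows$animal_id <- sprintf(
      "A%05.2f_%02d", animal_rows$activity_mbq, animal_rows$animal
    )
    series <- purrr::map_dfr(seq_len(nrow(animal_rows)), function(i) {
      p_i <- retention_params(
        params$fraction_fast, animal_rows$halftime_fast[i],
        params$fraction_slow, animal_rows$halftime_slow[i]
      )
      tibble::tibble(
        animal_id = animal_rows$animal_id[i],
        activity_mbq = animal_rows$activity_mbq[i],
        day = days,
        fraction_retained = retention_fraction(days, p_i)
      )
    })
    attr(series, "animal_params") <-
      animal_rows[, c("animal_id", "activity_mbq", "halftime_fast", "halftime_slow")]
    series
  })
}

# Expected value of a log-normal truncated above at `cap`.
lnorm_mean_below <- function(meanlog, sdlog, cap) {
  lc <- log(cap)
  exp(meanlog + sdlog^2 / 2) *
    pnorm((lc - meanlog - sdlog^2) / sdlog) / pnorm((lc - meanlog) / sdlog)
}

#' Generate a per-cell fluorescence sample
#'
#' Mixture of a log-normal "bulk" population truncated at the 3000 AU
#' exclusion cutoff and an apoptotic tail lying strictly above it (a
#' shifted log-normal). The bulk location is solved by 1-D root finding so
#' that the truncated-bulk mean - which is exactly the post-filter mean in
#' expectation, since the filter removes precisely the tail - equals
#' `target_mean`.
#'
#' @param target_mean Desired post-filter mean fluorescence in AU; must lie
#'   well below the cutoff (error above 2900 AU or at 0).
#' @param n_cells Number of cells to draw.
#' @param noise A [noise_config()].
#' @param seed Seed.
#' @param cutoff Apoptosis exclusion cutoff (AU).
#' @return Tibble with a single `fluorescence` column.
#' @export
generate_cells <- function(target_mean, n_cells, noise = noise_config(),
                           seed = 1, cutoff = 3000) {
  stopifnot(n_cells >= 1)
  if (!is.finite(target_mean) || target_mean <= 0 || target_mean > 0.97 * cutoff) {
    abort("`target_mean` must lie in (0, 0.97 * cutoff]: unattainable after filtering.")
  }
  sig <- noise$cell_sdlog
  root <- uniroot(
    function(mu) lnorm_mean_below(mu, sig, cutoff) - target_mean,
    interval = c(log(target_mean) - 5, log(cutoff) + 5 * sig),
    tol = 1e-10, extendInt = "upX"
  )
  mu <- root$root
  withr::with_seed(child_seed(seed, 307L), {
    n_tail <- stats::rbinom(1, n_cells, noise$tail_weight)
    n_bulk <- n_cells - n_tail
    bulk <- rlnorm(n_bulk, mu, sig)
    # resample the rare bulk draws above the cutoff (truncated log-normal)
    while (any(bulk > cutoff)) {
      idx <- bulk > cutoff
      bulk[idx] <- rlnorm(sum(idx), mu, sig)
    }
    tail_vals <- if (n_tail > 0) {
      cutoff + rlnorm(n_tail, noise$tail_meanlog, noise$tail_sdlog)
    } else {
      numeric(0)
    }
    tibble::tibble(fluorescence = sample(c(bulk, tail_vals)))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Composes the three generators into a self-consistent study: per-animal
#' retention curves, per-animal mean fluorescences (Gaussian around the
#' kinetic model), the group-level calibration table derived from them, and
#' optionally per-cell samples whose post-filter means target the
#' per-animal means (so cell-level aggregation reproduces the group table
#' within Monte-Carlo error).
#'
#' @param design A [study_design()] tibble.
#' @param truth Generating [h2ax_params()].
#' @param retention Population [retention_params()].
#' @param noise A [noise_config()].
#' @param seed Seed controlling every random stage.
#' @param cells Also generate per-cell samples (the slowest stage).
#' @param out_dir If non-`NULL`, write `group_means.csv`, `retention.csv`,
#'   optionally `cells.csv`, and `manifest.json` there.
#' @return List of class `study_bundle` with elements `design`,
#'   `group_means`, `animal_means`, `retention`, `cells` (or `NULL`),
#'   `truth`, `seed`.
#' @export
generate_full_study <- function(design = study_design(), truth = h2ax_params(),
                                retention = retention_params(),
                                noise = noise_config(), seed = 1,
                                cells = FALSE, out_dir = NULL) {
  check_columns(design, c("activity_mbq", "day", "n_animals"), "design")
  cells_range <- attr(design, "cells_range") %||% c(150, 500)

  animal_means <- withr::with_seed(child_seed(seed, 401L), {
    purrr::map_dfr(seq_len(nrow(design)), function(i) {
      a <- design$activity_mbq[i]
      d <- design$day[i]
      n <- design$n_animals[i]
      mu <- predict_fluorescence(truth, a, d)
      draw <- if (noise$group_sem > 0) {
        rnorm(n, mu, sqrt(n) * noise$group_sem)
      } else {
        rep(mu, n)
      }
      tibble::tibble(
        activity_mbq = a, day = d, animal = seq_len(n),
        animal_id = sprintf("A%05.2f_d%02d_%02d", a, d, seq_len(n)),
        animal_mean = pmax(draw, 50) # fluorescence cannot be negative
      )
    })
  })

  group_means <- animal_means |>
    dplyr::group_by(.data$activity_mbq, .data$day) |>
    dplyr::summarise(
      mean_fluorescence = mean(.data$animal_mean),
      sem = if (dplyr::n() > 1 && noise$group_sem > 0) {
        sd(.data$animal_mean) / sqrt(dplyr::n())
      } else {
        36
      },
      n = dplyr::n(), .groups = "drop"
    )

  retention_curves <- generate_retention_curves(
    design, params = retention, cv = noise$retention_cv,
    seed = child_seed(seed, 2L)
  )

  cell_table <- NULL
  if (cells) {
    n_cells_draw <- withr::with_seed(child_seed(seed, 503L), {
      sample(cells_range[1]:cells_range[2], nrow(animal_means), replace = TRUE)
    })
    cell_table <- purrr::map_dfr(seq_len(nrow(animal_means)), function(i) {
      cs <- generate_cells(
        target_mean = animal_means$animal_mean[i],
        n_cells = n_cells_draw[i], noise = noise,
        seed = child_seed(seed, 600L + i)
      )
      tibble::tibble(
        tissue = "blood",
        animal_id = animal_means$animal_id[i],
        activity_mbq = animal_means$activity_mbq[i],
        day = animal_means$day[i],
        fluorescence = cs$fluorescence
      )
    })
  }

  bundle <- structure(
    list(
      design = design, group_means = group_means, animal_means = animal_means,
      retention = retention_curves, cells = cell_table,
      truth = truth, seed = seed
    ),
    class = "study_bundle"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(group_means, file.path(out_dir, "group_means.csv"))
    readr::write_csv(retention_curves, file.path(out_dir, "retention.csv"))
    if (!is.null(cell_table)) {
      readr::write_csv(cell_table, file.path(out_dir, "cells.csv"))
    }
    manifest <- list(
      seed = seed,
      truth = unclass(truth),
      retention = unclass(retention),
      noise = unclass(noise),
      n_points = nrow(group_means),
      files = c("group_means.csv", "retention.csv",
        if (!is.null(cell_table)) "cells.csv")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  bundle
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf(
    "Synthetic study bundle (seed %s): %d group means, %d retention rows%s\n",
    format(x$seed), nrow(x$group_means), nrow(x$retention),
    if (is.null(x$cells)) "" else sprintf(", %d cells", nrow(x$cells))
  ))
  invisible(x)
}
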