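# Per-cell fluorescence screening and damage classification.
#
# Expected per-cell table: one row per scored cell with a `fluorescence`
# column (AU) and optional grouping columns `tissue`, `animal_id`,
# `activity_mbq`, `day`.

cell_group_cols <- function(data) {
  intersect(c("tissue", "activity_mbq", "day"), names(data))
}

#' Remove highly fluorescent (apoptotic) cells
#'
#' Cells with total fluorescence strictly above `cutoff` (default 3000 AU)
#' carry fragmented nuclear DNA and are removed before any mean is formed.
#' The inequality is strict: a cell exactly at the cutoff is kept.
#'
#' @param cells Per-cell data frame with a `fluorescence` column.
#' @param cutoff Exclusion threshold in AU.
#' @return The kept rows as a tibble, with attributes `n_removed` (count of
#'   excluded cells) and `hf_filtered = TRUE`. Warns if nothing survives.
#' @export
filter_high_fluorescence <- function(cells, cutoff = 3000) {
  check_columns(cells, "fluorescence", "cells")
  check_nonneg(cells$fluorescence, "fluorescence")
  keep <- cells$fluorescence <= cutoff
  kept <- tibble::as_tibble(cells[keep, , drop = FALSE])
  if (nrow(kept) == 0) {
    warn("All cells exceed the fluorescence cutoff; downstream means are undefined.")
  }
  attr(kept, "n_removed") <- sum(!keep)
  attr(kept, "hf_filtered") <- TRUE
  attr(kept, "cutoff") <- cutoff
  kept
}

#' Count healthy, intermediate and highly damaged cells
#'
#' Classifies each cell by its fluorescence: below `low_cutoff` (strict)
#' the cell is `"healthy"` (healthy or newly formed), above `high_cutoff`
#' (strict) it is `"damaged"` (highly damaged/dying); everything else,
#' including values exactly at a cutoff, is `"intermediate"`. Ratios are
#' reported both ways; a zero denominator yields `NA` with `ratio_flagged`.
#'
#' @param cells Per-cell data frame with a `fluorescence` column; counts
#'   are reported per combination of any of `tissue`, `activity_mbq`,
#'   `day` present.
#' @param low_cutoff,high_cutoff Classification thresholds in AU.
#' @return Tibble with the grouping columns plus `healthy`,
#'   `intermediate`, `damaged`, `damaged_over_healthy`,
#'   `healthy_over_damaged`, `ratio_flagged`.
#' @export
classify_damage <- function(cells, low_cutoff = 500, high_cutoff = 3000) {
  check_columns(cells, "fluorescence", "cells")
  if (low_cutoff >= high_cutoff) abort("`low_cutoff` must be below `high_cutoff`.")
  by <- cell_group_cols(cells)
  cells |>
    tibble::as_tibble() |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      healthy = sum(.data$fluorescence < low_cutoff),
      intermediate = sum(.data$fluorescence >= low_cutoff &
        .data$fluorescence <= high_cutoff),
      damaged = sum(.data$fluorescence > high_cutoff),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      damaged_over_healthy = ifelse(.data$healthy > 0,
        .data$damaged / .data$healthy, NA_real_
      ),
      healthy_over_damaged = ifelse(.data$damaged > 0,
        .data$healthy / .data$damaged, NA_real_
      ),
      ratio_flagged = .data$healthy == 0 | .data$damaged == 0
    )
}

#' Aggregate screened cells into group-level measurements
#'
#' Forms the group-level mean fluorescence, SEM and animal count used by
#' the model-fitting layer. The high-fluorescence filter is applied first
#' if it has not been already (this is the only path from cells to a group
#' measurement). Group SEM is computed over per-animal means - the
#' experimental unit is the animal, not the cell - so `sem = sd / sqrt(n)`
#' with `n` the number of animals; with `animal_level = FALSE` cells are
#' pooled instead and the SEM is over cells (for sensitivity checks only).
#' The pooled mean:median ratio is reported as a skewness diagnostic
#' (about 1 for the roughly symmetric filtered distributions).
#'
#' @param cells Per-cell data frame with `fluorescence` and `animal_id`
#'   columns plus grouping columns.
#' @param cutoff High-fluorescence exclusion cutoff (AU).
#' @param animal_level Compute SEM over per-animal means (default) or over
#'   pooled cells.
#' @return Tibble with grouping columns plus `mean_fluorescence`, `sem`,
#'   `n` (animals), `n_cells`, `mean_median_ratio`, `sem_flagged` (single
#'   animal).
#' @export
group_summary <- function(cells, cutoff = 3000, animal_level = TRUE) {
  check_columns(cells, c("fluorescence", "animal_id"), "cells")
  if (!isTRUE(attr(cells, "hf_filtered"))) {
    cells <- filter_high_fluorescence(cells, cutoff = cutoff)
  }
  if (nrow(cells) == 0) abort("No cells remain after filtering; group mean undefined.")
  by <- cell_group_cols(cells)

  pooled <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_median_ratio = mean(.data$fluorescence) / median(.data$fluorescence),
      pooled_mean = mean(.data$fluorescence),
      pooled_sem = sd(.data$fluorescence) / sqrt(dplyr::n()),
      .groups = "drop"
    )

  animals <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "animal_id")))) |>
    dplyr::summarise(animal_mean = mean(.data$fluorescence), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      group_mean = mean(.data$animal_mean),
      group_sem = sd(.data$animal_mean) / sqrt(dplyr::n()),
      n = dplyr::n(),
      .groups = "drop"
    )

  out <- dplyr::left_join(animals, pooled, by = by)
  out |>
    dplyr::mutate(
      mean_fluorescence = if (animal_level) .data$group_mean else .data$pooled_mean,
      sem = if (animal_level) .data$group_sem else .data$pooled_sem,
      sem_flagged = animal_level & .data$n < 2
    ) |>
    dplyr::select(dplyr::all_of(by), "mean_fluorescence", "sem", "n",
      "n_cells", "mean_median_ratio", "sem_flagged")
}
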