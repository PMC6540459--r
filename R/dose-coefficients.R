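# Time-dependent activity-to-dose conversion based on the measured
# committed-dose table of the four-activity mouse study (whole-body doses in
# Gy by administered activity and necropsy day, packaged as a plain-text
# fixture).

#' Measured committed-dose table of the study groups
#'
#' Whole-body committed doses (mean +/- SD, Gy) for the four administered
#' activities at each necropsy day, as measured by per-animal whole-body
#' counting in the mouse study this package emulates. Used to build
#' time-dependent activity-to-dose conversion coefficients.
#'
#' @return Tibble with columns `activity_mbq`, `day`, `committed_dose_gy`,
#'   `sd_gy`.
#' @export
committed_dose_table <- function() {
  path <- system.file("extdata", "committed_dose_by_group.csv",
    package = "h2axdosim", mustWork = TRUE
  )
  readr::read_csv(path, show_col_types = FALSE)
}

#' Time-dependent dose-conversion coefficients
#'
#' For each necropsy day, the coefficient is the mean over the four study
#' groups of committed dose divided by administered activity (Gy per MBq).
#'
#' @param table A committed-dose table as from [committed_dose_table()].
#' @return Tibble with columns `day`, `gy_per_mbq`.
#' @export
dose_coefficients <- function(table = committed_dose_table()) {
  check_columns(table, c("activity_mbq", "day", "committed_dose_gy"), "dose table")
  table |>
    dplyr::mutate(ratio = .data$committed_dose_gy / .data$activity_mbq) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(gy_per_mbq = mean(.data$ratio), .groups = "drop")
}

#' Convert activity estimates to committed dose
#'
#' Multiplies activities by the day-specific conversion coefficient. Days
#' outside the measured grid are an error unless `interpolate = TRUE`, in
#' which case linear interpolation inside the grid span is used (flagged by
#' a warning).
#'
#' @param activity_mbq Activities in MBq (vectorised).
#' @param day Days after injection (vectorised, recycled).
#' @param coeffs Coefficient table from [dose_coefficients()].
#' @param interpolate Allow linear interpolation between grid days.
#' @return Dose in Gy.
#' @export
activity_to_dose <- function(activity_mbq, day, coeffs = dose_coefficients(),
                             interpolate = FALSE) {
  check_nonneg(activity_mbq, "activity_mbq")
  n <- max(length(activity_mbq), length(day))
  a <- rep_len(activity_mbq, n)
  d <- rep_len(day, n)
  on_grid <- d %in% coeffs$day
  if (!all(on_grid)) {
    if (!interpolate) {
      abort(sprintf(
        "Day(s) %s are outside the coefficient grid {%s}; set `interpolate = TRUE` to interpolate.",
        paste(unique(d[!on_grid]), collapse = ", "),
        paste(coeffs$day, collapse = ", ")
      ))
    }
    if (any(d < min(coeffs$day) | d > max(coeffs$day))) {
      abort("Cannot extrapolate outside the coefficient grid.")
    }
    warn("Interpolating dose coefficients between measured days.")
  }
  cf <- approx(coeffs$day, coeffs$gy_per_mbq, xout = d)$y
  a * cf
}
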