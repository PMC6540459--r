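# Diagnostic plots. Each result type gets an autoplot() method so figures
# compose with the usual ggplot2 grammar.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_errorbar
#'   geom_abline geom_step labs theme_minimal
NULL

#' Plot fitted fluorescence kinetics over the data
#'
#' Group means with SEM error bars, overlaid with the fitted model curve
#' for each activity.
#'
#' @param object An [fit_h2ax()] result.
#' @param t_grid Time grid (days) for the fitted curves.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot h2ax_fit
#' @export
autoplot.h2ax_fit <- function(object, t_grid = seq(0.5, 14, by = 0.1), ...) {
  data <- dplyr::filter(object$data, .data$activity_mbq > 0)
  curves <- h2ax_curve(object$params, unique(data$activity_mbq), t_grid)
  ggplot(data, aes(x = .data$day, y = .data$mean_fluorescence,
    colour = factor(.data$activity_mbq))) +
    geom_errorbar(aes(
      ymin = .data$mean_fluorescence - .data$sem,
      ymax = .data$mean_fluorescence + .data$sem
    ), width = 0.2) +
    geom_point() +
    geom_line(data = curves, aes(y = .data$fluorescence)) +
    labs(
      x = "Days after injection", y = "Mean γ-H2AX fluorescence (AU)",
      colour = "Activity (MBq)"
    ) +
    theme_minimal()
}

#' Plot reconstructed against true injected activity
#'
#' Median Monte-Carlo estimates with min-max ranges against the true
#' activities, with the 1:1 line.
#'
#' @param object An `activity_estimates` tibble (see
#'   [summarize_estimates()]) with `true_activity_mbq`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activity_estimates
#' @export
autoplot.activity_estimates <- function(object, ...) {
  check_columns(object, "true_activity_mbq", "estimates")
  ggplot(object, aes(x = .data$true_activity_mbq, y = .data$median_activity,
    colour = factor(.data$day))) +
    geom_errorbar(aes(ymin = .data$min_activity, ymax = .data$max_activity),
      width = 0.1) +
    geom_point() +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    labs(
      x = "True injected activity (MBq)",
      y = "Reconstructed activity (MBq)", colour = "Day"
    ) +
    theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object An `roc_result` (see [classify_and_roc()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("AUC = %.3f (%.0f%% CI %.3f-%.3f)",
        object$auc, 100 * object$level, object$auc_ci[1], object$auc_ci[2])
    ) +
    theme_minimal()
}

#' Plot whole-body retention curves
#'
#' Per-animal retention series (thin lines) with the population curve.
#'
#' @param curves Tibble from [generate_retention_curves()] or a retention
#'   CSV with columns `animal_id`, `day`, `fraction_retained`.
#' @param params Population [retention_params()] for the reference curve.
#' @return A ggplot object.
#' @export
plot_retention <- function(curves, params = retention_params()) {
  check_columns(curves, c("animal_id", "day", "fraction_retained"), "curves")
  ref <- tibble::tibble(
    day = seq(0, max(curves$day), by = 0.1),
    fraction_retained = retention_fraction(seq(0, max(curves$day), by = 0.1), params)
  )
  ggplot(curves, aes(x = .data$day, y = 100 * .data$fraction_retained)) +
    geom_line(aes(group = .data$animal_id), alpha = 0.3) +
    geom_line(data = ref, colour = "red", linewidth = 1) +
    labs(x = "Days after injection", y = "Injected activity remaining (%)") +
    theme_minimal()
}
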