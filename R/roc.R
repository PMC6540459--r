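# Binary low/high activity classification from reconstructed activities,
# scored by an empirical ROC curve with a Mann-Whitney AUC and a DeLong
# confidence interval.

#' Classify reconstructed activities as low vs high and score with ROC
#'
#' Each data point is labelled by its true injected activity: `"low"` for
#' activities in `low_activities`, `"high"` for `high_activities`. Median
#' reconstructed activities are rescaled to \[0, 1\] by dividing by their
#' maximum and used as classification scores. The ROC curve is the
#' empirical threshold sweep; the AUC is computed by the Mann-Whitney
#' identity (ties counted 0.5) and its 95% CI by the DeLong variance with a
#' normal approximation, truncated to \[0, 1\].
#'
#' @param estimates An `activity_estimates` tibble with columns
#'   `median_activity` and `true_activity_mbq` (undefined points dropped).
#' @param low_activities,high_activities True activities (MBq) defining the
#'   two classes.
#' @param level Confidence level for the DeLong interval.
#' @return An object of class `roc_result`: list with `scores` (tibble of
#'   `score`, `label`), `roc_points` (tibble of `threshold`, `fpr`, `tpr`),
#'   `auc`, `auc_sweep` (trapezoid over the sweep; equals `auc`),
#'   `auc_ci`, `auc_var`, `n_low`, `n_high`.
#' @export
classify_and_roc <- function(estimates, low_activities = c(5.74, 6.66),
                             high_activities = c(7.65, 9.28), level = 0.95) {
  check_columns(estimates, c("median_activity", "true_activity_mbq"), "estimates")
  est <- estimates[is.finite(estimates$median_activity), ]
  is_low <- est$true_activity_mbq %in% low_activities
  is_high <- est$true_activity_mbq %in% high_activities
  est <- est[is_low | is_high, ]
  label <- ifelse(est$true_activity_mbq %in% high_activities, "high", "low")
  if (length(unique(label)) < 2) {
    abort("Both a low and a high class are required for ROC analysis.")
  }
  scores <- est$median_activity / max(est$median_activity)
  roc_from_scores(scores, label, level = level)
}

#' ROC analysis of arbitrary scores and binary labels
#'
#' Lower-level engine behind [classify_and_roc()]; exported so that score
#' sets from other pipelines can be assessed the same way.
#'
#' @param scores Numeric scores; higher means more likely `"high"`.
#' @param labels Character vector of `"low"` / `"high"` (or a factor whose
#'   second level is the positive class).
#' @param level Confidence level for the DeLong interval.
#' @return An object of class `roc_result` (see [classify_and_roc()]).
#' @export
roc_from_scores <- function(scores, labels, level = 0.95) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- scores[labels == "high"]
  neg <- scores[labels == "low"]
  m <- length(pos)
  n <- length(neg)
  if (m == 0 || n == 0) abort("Both classes must be nonempty.")

  # empirical threshold sweep: predict "high" when score >= threshold
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thresholds, function(th) mean(pos >= th), numeric(1))
  fpr <- vapply(thresholds, function(th) mean(neg >= th), numeric(1))
  roc_points <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr)

  # trapezoid under the sweep curve
  auc_sweep <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)

  # Mann-Whitney identity with midpoint tie handling, plus DeLong placements
  placements_pos <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  placements_neg <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  auc <- mean(placements_pos)
  s10 <- if (m > 1) stats::var(placements_pos) else 0
  s01 <- if (n > 1) stats::var(placements_neg) else 0
  auc_var <- s10 / m + s01 / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- c(
    max(0, auc - z * sqrt(auc_var)),
    min(1, auc + z * sqrt(auc_var))
  )

  structure(
    list(
      scores = tibble::tibble(score = scores, label = labels),
      roc_points = roc_points,
      auc = auc, auc_sweep = auc_sweep,
      auc_ci = ci, auc_var = auc_var,
      n_low = n, n_high = m, level = level
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC = %.3f (%.0f%% DeLong CI %.3f-%.3f; %d high vs %d low)\n",
    x$auc, 100 * x$level, x$auc_ci[1], x$auc_ci[2], x$n_high, x$n_low
  ))
  invisible(x)
}

#' @rdname classify_and_roc
#' @param x An `roc_result` object.
#' @param ... Unused.
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
    n_low = x$n_low, n_high = x$n_high
  )
}
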