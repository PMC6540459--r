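# Monte-Carlo biodosimetry: propagate calibration-curve uncertainty into
# injected-activity estimates by sampling kinetic-parameter combinations
# from the joint confidence region and inverting the forward model for each.

#' Sample kinetic-parameter combinations from the joint confidence region
#'
#' Draws parameter combinations by perturbing the best fit with independent
#' log-normal proposals (Gaussian on the transformed scale: log for
#' `k`, `alpha`, `r`; logit for `p`) and keeping those that satisfy
#' [in_confidence_region()] at the requested level, until at least `n_min`
#' draws are accepted. The proposal scale defaults to the profile-interval
#' half-widths on the transformed scale (computed on the fly if the fit
#' carries no intervals), which keeps the acceptance rate workable.
#'
#' @param fit A converged [fit_h2ax()] result.
#' @param n_min Minimum number of accepted draws (ensemble size).
#' @param seed Seed for the proposal stream.
#' @param level Confidence level of the joint region.
#' @param scale Optional numeric(4) proposal standard deviations on the
#'   transformed scale for `(k, alpha, r, p)`; overrides the automatic
#'   tuning.
#' @param df Degrees of freedom of the joint region (see
#'   [in_confidence_region()]).
#' @return An object of class `parameter_ensemble`: a list with `draws`
#'   (tibble of `k`, `alpha`, `r`, `p`), `background`, `n_draws`, `seed`,
#'   `scale`, `acceptance_rate`, `level`, `df`, and the originating `fit`.
#' @export
sample_confidence_region <- function(fit, n_min = 5000, seed = 1, level = 0.95,
                                     scale = NULL, df = 4) {
  stopifnot(inherits(fit, "h2ax_fit"), n_min >= 1)
  if (!fit$converged) abort("`fit` did not converge; cannot sample its confidence region.")
  theta <- fit$theta
  if (is.null(scale)) {
    ci <- fit$ci
    if (is.null(ci)) {
      ci <- purrr::map_dfr(free_param_names, function(pn) profile_ci(fit, pn, level = level))
    }
    ci <- ci[match(free_param_names, ci$term), ]
    trans <- function(v, j) if (j == 4) qlogis(v) else log(v)
    scale <- vapply(1:4, function(j) {
      lo <- ci$conf.low[j]; hi <- ci$conf.high[j]
      if (ci$low_open[j] || ci$high_open[j] || !is.finite(lo) || !is.finite(hi) ||
        lo <= 0 || hi <= 0 || (j == 4 && hi >= 1)) {
        return(0.15)
      }
      (trans(hi, j) - trans(lo, j)) / (2 * 1.96)
    }, numeric(1))
    scale <- pmax(scale, 1e-4)
  }
  stopifnot(length(scale) == 4, all(scale > 0))

  threshold <- qchisq(level, df = df)
  nll_best <- fit$nll
  data <- fit$data
  b <- fit$background

  accepted <- vector("list", 0)
  n_acc <- 0L
  n_prop <- 0L
  chunk <- max(1000L, n_min)
  withr::with_seed(child_seed(seed, 37L), {
    repeat {
      prop <- matrix(rnorm(4L * chunk, mean = rep(theta, each = chunk),
        sd = rep(scale, each = chunk)), ncol = 4)
      in_box <- if (is.null(fit$theta_lower)) rep(TRUE, chunk) else {
        apply(prop, 1, function(th) {
          all(th >= fit$theta_lower) && all(th <= fit$theta_upper)
        })
      }
      keep <- vapply(seq_len(chunk), function(i) {
        if (!in_box[i]) return(FALSE)
        params <- tryCatch(theta_to_params(prop[i, ], b), error = function(e) NULL)
        if (is.null(params)) return(FALSE)
        nll <- h2ax_nll(params, data)
        is.finite(nll) && 2 * (nll - nll_best) <= threshold
      }, logical(1))
      n_prop <- n_prop + chunk
      if (any(keep)) {
        accepted[[length(accepted) + 1]] <- prop[keep, , drop = FALSE]
        n_acc <- n_acc + sum(keep)
      }
      if (n_acc >= n_min) break
      if (n_prop >= 50 * n_min && n_acc / n_prop < 1e-4) {
        abort(sprintf(
          "Acceptance rate %.2g after %d proposals; reduce `scale` (current max %.3g).",
          n_acc / n_prop, n_prop, max(scale)
        ))
      }
    }
  })
  thetas <- do.call(rbind, accepted)[seq_len(n_min), , drop = FALSE]
  draws <- tibble::tibble(
    k = exp(thetas[, 1]), alpha = exp(thetas[, 2]),
    r = exp(thetas[, 3]), p = plogis(thetas[, 4])
  )
  structure(
    list(
      draws = draws, background = b, n_draws = nrow(draws), seed = seed,
      scale = scale, acceptance_rate = n_acc / n_prop, level = level, df = df,
      fit = fit
    ),
    class = "parameter_ensemble"
  )
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf(
    "Confidence-region ensemble: %d draws (level %.2f, df %d, acceptance %.1f%%)\n",
    x$n_draws, x$level, x$df, 100 * x$acceptance_rate
  ))
  invisible(x)
}

#' Invert the kinetic model for injected activity
#'
#' Given one parameter combination, a time, and a measured fluorescence
#' `F_j`, finds the activity minimising the squared calibration-curve
#' mismatch `f = [F(psi, t, A) - F_j]^2` by bounded 1-D minimisation.
#'
#' The activity response `g(A) = k A exp(-alpha A)` peaks at `A = 1/alpha`,
#' so a measured fluorescence generally corresponds to two activities. The
#' `branch` argument selects the root: `"high"` (default) restricts to the
#' decreasing limb `A >= 1/alpha`, where all study activities lie; `"low"`
#' to `A <= 1/alpha`; `"global"` evaluates both and returns the smaller
#' mismatch, ties going to `"high"`.
#'
#' Fluorescence outside the attainable range on the branch is not an error:
#' a value above the model maximum (at `A = 1/alpha`) returns `1/alpha`
#' flagged `"saturated"`, and a value below the branch minimum returns the
#' search boundary flagged `"out_of_range"`.
#'
#' @param params An [h2ax_params()] object (one ensemble draw).
#' @param time Days after injection (> 0).
#' @param fluorescence Measured mean fluorescence in AU.
#' @param search Activity search interval in MBq.
#' @param branch `"high"`, `"low"`, or `"global"`.
#' @return List with `estimate` (MBq), `flag` (`"ok"`, `"out_of_range"`,
#'   `"saturated"`), and `objective` (the minimised squared mismatch).
#' @export
estimate_activity <- function(params, time, fluorescence,
                              search = c(0.1, 20),
                              branch = c("high", "low", "global")) {
  branch <- match.arg(branch)
  stopifnot(time > 0, length(search) == 2, search[1] > 0, search[2] > search[1])
  a_peak <- activity_of_max_response(params)
  f_of <- function(a) predict_fluorescence(params, a, time)

  one_branch <- function(which) {
    interval <- if (which == "high") {
      c(max(search[1], min(a_peak, search[2])), search[2])
    } else {
      c(search[1], min(search[2], max(a_peak, search[1])))
    }
    f_peak_end <- f_of(if (which == "high") interval[1] else interval[2])
    f_far_end <- f_of(if (which == "high") interval[2] else interval[1])
    if (fluorescence > f_peak_end) {
      a_hat <- if (which == "high") interval[1] else interval[2]
      return(list(
        estimate = a_hat, flag = "saturated",
        objective = (f_peak_end - fluorescence)^2
      ))
    }
    if (fluorescence < f_far_end) {
      a_hat <- if (which == "high") interval[2] else interval[1]
      return(list(
        estimate = a_hat, flag = "out_of_range",
        objective = (f_far_end - fluorescence)^2
      ))
    }
    opt <- optimize(function(a) (f_of(a) - fluorescence)^2,
      interval = interval, tol = 1e-9
    )
    list(estimate = opt$minimum, flag = "ok", objective = opt$objective)
  }

  if (branch == "global") {
    hi <- one_branch("high")
    lo <- one_branch("low")
    if (lo$objective < hi$objective) lo else hi
  } else {
    one_branch(branch)
  }
}

#' Summarise per-draw activity estimates for a set of data points
#'
#' Runs [estimate_activity()] for every ensemble draw at every data point
#' and reports the median, minimum and maximum of the accepted (unflagged)
#' per-draw estimates, as used when comparing reconstructed with true
#' injected activities.
#'
#' @param ensemble A [sample_confidence_region()] result.
#' @param points Data frame with columns `day` and `mean_fluorescence`;
#'   an optional `true_activity_mbq` column is carried through for scoring.
#' @param search,branch Passed to [estimate_activity()].
#' @param keep_draws If `TRUE`, attach the per-draw estimate matrix as
#'   attribute `"draw_estimates"`.
#' @return Tibble of class `activity_estimates` with one row per point:
#'   `day`, `mean_fluorescence`, (`true_activity_mbq`,) `median_activity`,
#'   `min_activity`, `max_activity`, `n_used`, `n_flagged`, `undefined`.
#' @export
summarize_estimates <- function(ensemble, points, search = c(0.1, 20),
                                branch = "high", keep_draws = FALSE) {
  stopifnot(inherits(ensemble, "parameter_ensemble"))
  check_columns(points, c("day", "mean_fluorescence"), "points")
  if (nrow(points) == 0) abort("`points` must contain at least one row.")
  draws <- ensemble$draws
  b <- ensemble$background

  per_point <- purrr::map_dfr(seq_len(nrow(points)), function(jj) {
    tj <- points$day[jj]
    fj <- points$mean_fluorescence[jj]
    res <- lapply(seq_len(nrow(draws)), function(i) {
      psi <- h2ax_params(
        k = draws$k[i], alpha = draws$alpha[i],
        r = draws$r[i], p = draws$p[i], b = b
      )
      estimate_activity(psi, tj, fj, search = search, branch = branch)
    })
    est <- vapply(res, `[[`, numeric(1), "estimate")
    flag <- vapply(res, `[[`, character(1), "flag")
    ok <- flag == "ok"
    out <- tibble::tibble(
      day = tj, mean_fluorescence = fj,
      median_activity = if (any(ok)) median(est[ok]) else NA_real_,
      min_activity = if (any(ok)) min(est[ok]) else NA_real_,
      max_activity = if (any(ok)) max(est[ok]) else NA_real_,
      n_used = sum(ok), n_flagged = sum(!ok), undefined = !any(ok)
    )
    if (keep_draws) out$draw_estimates <- list(est)
    out
  })
  if ("true_activity_mbq" %in% names(points)) {
    per_point <- tibble::add_column(per_point,
      true_activity_mbq = points$true_activity_mbq,
      .after = "mean_fluorescence"
    )
  }
  class(per_point) <- c("activity_estimates", class(per_point))
  per_point
}

default_time_ranges <- list(c(2, 3), c(2, 5), c(2, 7), c(2, 14))

#' Correlations between true and reconstructed activity over time windows
#'
#' For each `(d_lo, d_hi)` window, correlates the true injected activities
#' with the median reconstructed activities of all points whose measurement
#' day falls inside the window. Pearson's r comes with a two-sided p-value
#' from the t-distribution (n - 2 df); Spearman's rho uses an exact
#' permutation p-value when n <= 9 (no p-value convention is standard for
#' these small calibration tables, so both are reported).
#'
#' @param estimates An `activity_estimates` tibble containing
#'   `true_activity_mbq` (see [summarize_estimates()]). Undefined points
#'   are dropped.
#' @param time_ranges List of `c(d_lo, d_hi)` day windows.
#' @return Tibble with one row per window: `range`, `n`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `flagged`.
#' @export
correlation_report <- function(estimates, time_ranges = default_time_ranges) {
  check_columns(estimates, c("day", "median_activity", "true_activity_mbq"), "estimates")
  est <- estimates[!isTRUE_vec(estimates$undefined) & is.finite(estimates$median_activity), ]
  purrr::map_dfr(time_ranges, function(rng) {
    sub <- est[est$day >= rng[1] & est$day <= rng[2], ]
    label <- sprintf("%g-%g days", rng[1], rng[2])
    n <- nrow(sub)
    if (n < 3 || sd(sub$true_activity_mbq) == 0 || sd(sub$median_activity) == 0) {
      return(tibble::tibble(
        range = label, n = n, pearson_r = NA_real_, pearson_p = NA_real_,
        spearman_rho = NA_real_, spearman_p = NA_real_, flagged = TRUE
      ))
    }
    pe <- cor.test(sub$true_activity_mbq, sub$median_activity, method = "pearson")
    sp <- suppressWarnings(cor.test(
      sub$true_activity_mbq, sub$median_activity,
      method = "spearman", exact = n <= 9
    ))
    tibble::tibble(
      range = label, n = n,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      flagged = FALSE
    )
  })
}

isTRUE_vec <- function(x) {
  if (is.null(x)) return(FALSE)
  !is.na(x) & x
}
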