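#' Percent variation of a set of group means
#'
#' Spread of a vector expressed as a percentage of its maximum,
#' `100 * (max - min) / max`. Used to summarise how stable control-group
#' fluorescence backgrounds are across necropsy days.
#'
#' @param x Numeric vector of group means (all positive).
#' @return A single percentage.
#' @examples
#' percent_variation(c(1026, 972)) # ~5.3
#' @export
percent_variation <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(is.finite(x)), all(x > 0))
  100 * (max(x) - min(x)) / max(x)
}

# shared input checks -------------------------------------------------------

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and >= 0.", name))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

# Derive a stream-specific child seed from a user seed, staying inside the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}
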