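# Shared fixtures, built in code. The "truth" parameters are the package
# defaults (the published best-fit kinetics); expensive objects are cached
# per test run.

truth <- h2ax_params()
design5 <- study_design()

# zero-noise calibration table on the full study design
noisefree_means <- generate_group_means(
  design5, truth, noise_config(group_sem = 0), seed = 1
)

.fixture_cache <- new.env(parent = emptyenv())

# zero-noise fit, reused by several files (deterministic)
noisefree_fit <- function() {
  if (is.null(.fixture_cache$fit0)) {
    .fixture_cache$fit0 <- fit_h2ax(
      noisefree_means, background = 1006, n_starts = 12, seed = 1
    )
  }
  .fixture_cache$fit0
}

as_params <- function(row, b = 1006) {
  h2ax_params(k = row$k, alpha = row$alpha, r = row$r, p = row$p, b = b)
}
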