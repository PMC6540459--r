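# h2axdosim

Radiation biodosimetry for **protracted internal exposure to Cs-137**,
built around the γ-H2AX DNA damage biomarker in blood mononuclear cells.

After incorporation of soluble Cs-137 (the radionuclide of greatest
concern in "dirty bomb" and reactor-accident scenarios), the body is
irradiated continuously at a falling dose rate while the activity is
excreted. Unlike after an acute exposure — where γ-H2AX signal resolves in
a day or two — the signal stays elevated for weeks, which makes it usable
for triage: *given a blood sample drawn `t` days after the incident, how
much activity was incorporated?* This package implements that analysis for
the mouse model system, end to end and fully tested, for biostatisticians
and radiation researchers working on internal-emitter biodosimetry.

## The models

**Biokinetics and dose.** Whole-body retention is biexponential,

    R(t) = 0.20 exp(−0.693 t / 0.6) + 0.80 exp(−0.693 t / 7.8)   (t in days)

giving cumulative disintegrations, dose coefficients (× SEE, the specific
effective energy per disintegration), committed dose `D = A × D/A`, and
daily dose rates by day-over-day differencing. About half the activity is
excreted by day 5.

**γ-H2AX kinetics.** Mean fluorescence (arbitrary units) after injecting
activity `A` (MBq), measured `t` days later:

    F(A, t) = b + k·A·t·exp[ −αA + 1 − (1 + r t)^p ]

a rapid activity-dependent rise (`k`), attenuation at high activity from
death of heavily damaged cells (`α`), and a stretched-exponential decline
(`r`, `p`) from excretion, repair and cell turnover. The activity response
`k·A·e^{−αA}` peaks at `A = 1/α ≈ 3.9 MBq`; the calibrated activities all
lie on its decreasing limb.

**Calibration and inversion.** The model is fitted to group means by
weighted Gaussian maximum likelihood (weights `1/SEM²`, background `b`
fixed at the control level), with profile-likelihood 95% intervals. For
biodosimetry, ≥5000 parameter combinations are sampled from the joint 95%
confidence region and the calibration curve is inverted for each
(`argmin [F(ψᵢ, tⱼ, A) − Fⱼ]²`), giving median and range activity
estimates per data point, correlation reports over time windows, an ROC
analysis of low- vs high-activity classification (Mann–Whitney AUC,
DeLong CI), and dose conversion via the measured committed-dose table.

A seeded synthetic-study generator reproduces the emulated design (four
activities 5.74–9.28 MBq plus control, necropsy days 2–14, 8 mice per
point, 150–500 scored cells per sample), so every stage is testable
without any data download. See the methods vignette
(`vignettes/biodosimetry-methods.Rmd`) for assumptions, parameter
meanings, numerical choices and limitations.

## Worked example

```r
library(h2axdosim)

params <- h2ax_params()          # reported best-fit kinetics
retention_fraction(5)            # 0.5136748  -> ~49% excreted by day 5
predict_fluorescence(params, 5.74, 2)   # 1312.492 AU at 5.74 MBq, day 2

# simulate a study, calibrate, invert, and score (one seed controls it all)
result <- run_pipeline(pipeline_config(seed = 42, n_draws = 1000, n_starts = 8))
result
#> Biodosimetry pipeline result
#> gamma-H2AX model fit: NLL = 128.6372, weighted SSR = 42.2370 (25 points)
#> gamma-H2AX kinetic parameters
#>   k = 5.365e+06 AU/MBq/day, alpha = 0.2692 /MBq, r = 1e+08 /day, p = 0.1281, b = 1006 AU
#> Profile-likelihood intervals:
#>   term     estimate     conf.low conf.high low_open high_open
#>      k 5.365158e+06 3.575243e+04       Inf    FALSE      TRUE
#>  alpha 2.691818e-01 2.138573e-01 0.3283944    FALSE     FALSE
#>      r 1.000000e+08 0.000000e+00       Inf     TRUE      TRUE
#>      p 1.281212e-01 1.252260e-01 0.2028065    FALSE     FALSE
#>
#> Correlations (true vs reconstructed activity):
#>      range  n pearson_r   pearson_p spearman_rho spearman_p flagged
#>   2-3 days  8 0.7962190 0.018054287    0.6343350 0.09116266   FALSE
#>   2-5 days 12 0.7038722 0.010626245    0.5829752 0.04665076   FALSE
#>   2-7 days 16 0.6863812 0.003321199    0.5457052 0.02877403   FALSE
#>  2-14 days 19 0.6598523 0.002111463    0.4626756 0.04607503   FALSE
#>
#> ROC: AUC = 0.711 (95% DeLong CI 0.457-0.965; 9 high vs 10 low)
```

Reading the output: `α` is recovered tightly (0.21–0.33 around the true
0.255) while `k` and `r` have enormous intervals — they trade off along a
likelihood ridge, a genuine property of the model discussed in the
vignette. Activity reconstruction correlates best with truth in the first
days after injection and degrades as the activity curves converge; the ROC
says this particular simulated study separates low from high activities
only moderately (the synthetic noise level is deliberately realistic).
Every result type has `tidy()`/`glance()` and `autoplot()` methods:

```r
tidy(result$fit)                 # parameter table with profile CIs
autoplot(result$fit)             # data + fitted kinetics
autoplot(result$estimates)       # reconstructed vs true activity
autoplot(result$roc)             # ROC curve
```

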