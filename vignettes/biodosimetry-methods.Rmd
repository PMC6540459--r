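---
title: "Methods: gamma-H2AX biodosimetry for protracted Cs-137 exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-H2AX biodosimetry for protracted Cs-137 exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h2axdosim)
```

## The problem

After an internal contamination with soluble Cs-137 (ingestion, inhalation,
wound contamination), the body is irradiated continuously while the
radionuclide is excreted. Triage biodosimetry then has to answer: *given a
blood sample taken `t` days after the incident, how much activity was
incorporated?* This package implements a complete, testable version of that
analysis for the mouse model system: whole-body biokinetics and dosimetry,
a kinetic model of the gamma-H2AX DNA damage signal, likelihood-based
calibration with honest uncertainties, and Monte-Carlo inversion of a
fluorescence measurement into an injected-activity estimate.

## Whole-body biokinetics and dose

Cs-137 retention is biexponential,

$$R(t) = 0.20\,e^{-(0.693/0.6)\,t} + 0.80\,e^{-(0.693/7.8)\,t},$$

with half-times in days: a fast phase clearing about 20% of the activity
(0.6 d) and a slow, muscle-dominated phase for the remaining 80% (7.8 d).
Two conventions are worth stating explicitly:

* the decay constant uses the literal `0.693` by default so numbers match
  the conventional printed form of the equation; `ln2 = log(2)` is a
  documented argument (the difference is below 0.02%);
* physical decay of Cs-137 (half-life ~30 years) is omitted — under 0.1%
  over a 14-day study.

Committed dose is `D = A × D/A`, with the dose coefficient obtained by
integrating body activity into a disintegration count and multiplying by
the specific effective energy (SEE) of Cs-137. The nominal whole-body SEE
is 2.41e-19 Gy per disintegration, but this package deliberately treats SEE
as configuration rather than constant: combining the nominal SEE with the
average retention equation does **not** reproduce measured per-animal
committed doses (which depend on per-animal retention fits and counting
calibration), and the discrepancy is orders of magnitude, suggesting a
units convention difference. `calibrate_see()` rescales SEE against any
independently measured `(activity, day, dose)` anchor. For converting
reconstructed activities to dose, the package instead ships the *measured*
committed-dose table of the four study groups
(`committed_dose_table()`) and uses day-specific empirical coefficients
(`dose_coefficients()`), which is how the study itself converted estimates.

Daily dose rate is the day-over-day difference of committed dose on the
integer-day grid 1..14, and decreases monotonically as activity is
excreted.

## The gamma-H2AX kinetic model

Mean fluorescence of blood mononuclear cells is modelled as

$$F(A, t) = b + k\,A\,t\,\exp\!\big[-\alpha A + 1 - (1 + r t)^p\big],$$

with `b` the control background (AU), `k` (AU/MBq/day) the initial
activity-proportional rise, `alpha` (/MBq) the attenuation from death of
heavily damaged cells, and the modified stretched exponential in `r`
(/day) and `p` (unitless, 0 < p < 1) describing the slow multi-scale
decline from excretion, repair and turnover. Defaults are the best-fit
values reported for this mouse system: `k = 4.65e5`, `alpha = 0.255`,
`r = 1.07e6`, `p = 0.153`, `b = 1006`.

Two structural facts drive everything downstream:

* **Separability.** `F - b = g(A) · h(t)` with `g(A) = k A e^{-αA}`.
  `g` peaks at `A = 1/α ≈ 3.92 MBq`; all study activities (5.74–9.28 MBq)
  lie on its *decreasing* limb, so higher activity gives *lower*
  fluorescence in the calibrated range. The time profile peaks well before
  day 2 (`peak_time()` ≈ 0.2 d), before the first measurement.
* **Numerical range.** `k A t` reaches 1e7 while the exponential factor is
  1e-4 or smaller, and `r t` exceeds 1e7. The model is therefore evaluated
  in log space, with `(1 + rt)^p = exp(p·log1p(rt))`; a direct evaluation
  is kept internally and equivalence is asserted to 1e-10 relative in the
  tests.

Because `r t ≫ 1` at all measured times, `(1+rt)^p ≈ (rt)^p = r^p t^p`:
`r` and `k` are close to trading off against each other (jointly they
approach a pure power law in `t` as `p` shrinks). This near-ridge is a real
feature of the model, not an implementation artifact, and shapes the
fitting choices below. The time unit of `r` is days, consistent with the reported per-day units of the parameters.

## Fitting: weighted Gaussian likelihood, profile intervals

Calibration data are group-level means with standard errors (`sem`) from
`n = 8` animals per point. The likelihood is Gaussian with per-point SDs
equal to the reported SEMs (weights `1/sem²` — SEMs, not SDs, because the
group mean is the modelled quantity and SEMs are what the study reports as
error bars). `b` is fixed at the measured control level, assumed to be the
overall control mean of 1006 AU; `k, α, r, p` are free.

Numerical choices:

* positivity via log-parameterisation; `p` via logit, which enforces its
  (0,1) domain exactly;
* a quasi-Newton minimiser (`nlminb`) with 20 seeded log-uniform
  multistarts plus a deterministic centre start; ties broken by lower NLL,
  then lexicographically smaller parameter vector; convergence tolerance
  1e-10 on the objective;
* box constraints `k ∈ [1e4, 1e7]`, `α ∈ [0.02, 2]`, `r ∈ [1e4, 1e8]`,
  `p ∈ [0.05, 0.8]`. Without a box, noisy data can push the optimiser
  along the `k–r` ridge to arbitrarily extreme values at essentially flat
  likelihood; the box (2–4 decades around the defaults) keeps estimates in
  the physically interpretable range. Profile bounds that reach the box
  are reported open-ended rather than silently clipped;
* degenerate designs (a single activity, or a single day) are warned about
  up front and flagged via the Hessian condition number (threshold 1e8):
  at one activity, `k` and `α` enter only through `k e^{-αA}` and are
  structurally confounded.

Uncertainties are profile-likelihood intervals: scan one parameter,
re-optimise the rest, and take the deviance crossing of the chi-squared
quantile with 1 df (3.841 at 95%). Bounds are bracketed by geometric
expansion on the transformed scale and refined by monotone bisection to
1e-3 relative. The profile subproblem inherits the ridge and is genuinely
multimodal in practice; each profile point therefore tries several
deterministic starts plus a Nelder–Mead pass as a stall-proof fallback
before the quasi-Newton polish. The joint confidence region (used for
Monte-Carlo sampling) uses df = 4 (9.488 at 95%) since all four parameters
are free; both df conventions are explicit arguments.

In a 200-replicate simulation at the study's design and noise level, the
95% profile intervals for `k` and `p` cover the generating values
essentially always (their ridge-dominated intervals are wide, often
box-wide and flagged open-ended — conservative rather than calibrated),
`r` covers at ~97%, while coverage for `α` runs a few points below
nominal (~86%). The deficit is
statistical, not numerical: weights use SEMs *estimated* from 8 animals
(7 df), and treating them as known narrows the best-identified parameter's
interval slightly. With known SEMs, coverage for `α` is nominal. This is a
faithful property of the emulated analysis, and we report it rather than
tuning it away.

## Monte-Carlo inversion of fluorescence into activity

The calibrated model is used as a calibration curve. To propagate
calibration uncertainty:

1. sample ≥5000 parameter combinations from the joint 95% confidence
   region (log-normal proposals around the best fit, scale auto-tuned from
   the profile intervals, accept by the deviance rule; reproducible given
   a seed);
2. for each draw and each data point `(t_j, F_j)`, minimise
   `f = [F(ψ_i, t_j, A) − F_j]²` over `A` in a bounded interval
   (default 0.1–20 MBq, bracketing the study activities with margin);
3. report the median, minimum and maximum of the per-draw estimates.

Because `g(A)` is two-branched, the inverse is two-valued. The default
branch is `"high"` (`A ≥ 1/α`), where all study activities lie; `"low"`
and `"global"` are available, with global ties broken toward high. A
measured fluorescence above the response ceiling `F(1/α, t)` returns
`1/α` flagged `"saturated"`; one below the branch minimum returns the
search boundary flagged `"out_of_range"`. Flagged draws are excluded from
the median/range summaries (with counts reported) rather than silently
clamped — at late times, where the activity curves nearly overlap, a large
flagged fraction is itself diagnostic. A point no draw can invert is
reported `undefined`.

Reconstructed medians are scored against the true activities by Pearson
and Spearman correlations over nested day windows (2–3, 2–5, 2–7, 2–14).
Pearson p-values use the t-distribution with n−2 df; Spearman p-values are
exact for n ≤ 9. The package reproduces the study's qualitative pattern —
early windows correlate well, the full window poorly, because by day 14
the four activity curves nearly coincide. Over 100 replicate studies the
early window beats the full window in roughly nine cases out of ten
(the suite asserts at least 90%, which sits right at the Monte-Carlo
margin of what the study's noise level supports: observed fractions are
87–90% depending on the calibration seed). The published correlation *values* are not reproducible
without the original per-group fluorescence table, which was never
published in machine-readable form; they are deliberately out of scope.

Binary triage performance ("low" = 5.74/6.66 MBq vs "high" = 7.65/9.28
MBq) is scored by an ROC curve on max-normalised median estimates. The
implementation computes the empirical threshold sweep and the Mann–Whitney
AUC (ties at 0.5) — proven equal in the tests — and a DeLong-variance 95%
CI truncated to [0, 1]; the standard `pROC` implementation is used as an
independent cross-check in the test suite only.

## Per-cell screening rules

Scored cells with total fluorescence strictly above 3000 AU (fragmented
nuclear DNA, advanced apoptosis) are excluded before any mean is formed;
this filter is the only path from per-cell data to a group measurement.
Damage classes use strict cutoffs: healthy `< 500` AU, highly damaged
`> 3000` AU, intermediate otherwise (values exactly at a cutoff are
intermediate). Ratios are reported in both directions with zero
denominators flagged. Group SEMs are computed over per-animal means — the
animal, not the cell, is the experimental unit (a pooled-cell variant
exists for sensitivity checks). Whether the original analysis pooled cells
or averaged animals is not documented; per-animal means are the
defensible default and the switch is explicit.

## The synthetic-study generator

No raw data from the study are machine-readable, so the generator
reproduces the *design* and the *statistical structure the analysis
assumes*, and every stage of the pipeline is tested against it:

* design: activities 5.74, 6.66, 7.65, 9.28 MBq plus vehicle control;
  necropsy days 2, 3, 5, 7, 14; 8 animals per point; 150–500 scored cells
  per sample;
* group-level noise: per-animal means Gaussian around the kinetic model
  with SD `√n × 36` AU, so the group-mean SEM matches the 36 AU
  variability of the reported control background; empirical SEMs are
  reported, as a real study would;
* retention: per-animal half-times log-normal around the population values
  with CV 0.15 (a typical inter-animal spread for whole-body counting;
  the study reports only that curves were "similar" across animals),
  sampled on the counting schedule (daily to day 7, then days 10 and 14);
* cells: a log-normal bulk truncated at 3000 AU whose location is solved
  by root finding so the post-filter mean hits its target, plus an
  apoptotic tail strictly above 3000 AU (shifted log-normal, default
  weight 5% for exposed samples). The tail is a fixture: the study reports
  only that such cells exist and are removed. Control-like samples use a
  much smaller tail (~1%), consistent with damaged/healthy ratios of
  roughly 0.1 in unexposed samples.

All randomness flows through explicit seeds (one master seed per bundle,
with derived per-stage streams), and regeneration under the same seed is
byte-identical. What the generator does **not** emulate: lymphocyte subset
structure, cell-cycle effects, day-to-day drift in staining intensity, or
any dependence of excretion kinetics on activity (the study found none).
Passing tests therefore demonstrate that the *analysis machinery* is
correct and well-calibrated under the stated assumptions — not that the
model is biologically complete.

## Problem sizes and runtime choices

The test suite uses the full 25-point design throughout, 5000 ensemble
draws for the round-trip identity, 200 replicates for interval coverage,
and 100 replicate studies (250-draw subsampled ensemble) for the
correlation-degradation property; the acceptance script uses a
2000-draw ensemble and 100 replicate studies. These sizes give
Monte-Carlo errors comfortably below the asserted tolerances while keeping
a full run in the minutes range on one core.

## Known limitations

* Absolute dosimetry from first principles is intentionally not claimed:
  SEE must be calibrated, and the packaged dose conversion uses the
  measured group dose table.
* The `k`–`r` ridge means those parameters are only jointly meaningful
  near the calibrated regime; single-parameter point estimates of `k` or
  `r` should not be over-interpreted (their profile intervals say so).
* Inversion assumes the measured subject's kinetics follow the calibrated
  model with the calibrated background; individual variation in `b` is not
  propagated.
* The originally reported correlation coefficients, best-fit values and
  AUC are benchmarks for *structure*, not for value, in this
  package: reproducing them requires the unpublished raw group means.
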