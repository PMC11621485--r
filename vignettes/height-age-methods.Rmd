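---
title: "Height-age and the proportion of maximal benefit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Height-age and the proportion of maximal benefit: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heightage)
```

## The model

A growth standard represented by the LMS method tabulates, per sex and
day of age, a power `L`, a median `M(t)` (cm) and a coefficient of
variation `S(t)`. For the 0–5 y length/height-for-age standard the power
is 1 on every row, so a stature `y` at age `t` has z-score
`z = (y / M(t) - 1) / S(t)`, and a published mean z-score back-calculates
to a mean stature `y = M(t) (1 + z S(t))`. This package supports `L = 1`
references only and refuses anything else at load time.

**Height-age** is the age at which the standard's median stature equals a
group's observed mean stature. It is a *group-level* construct: the
expectation that growth tracks the median is defensible for a population
mean, not for an individual child. Because skeletal maturation is delayed
under growth-inhibiting conditions, a faltered group's height-age lags
its chronologic age and approximates its average skeletal age, and the
realistic benchmark for growth is the rate expected at that height-age.
On a height-age-for-age plot, that benchmark is a line of slope 1.

**Proportion of maximal benefit.** Over a common observation period, let
`ΔHA_I` and `ΔHA_C` be the intervention and control arms' changes in
height-age and `ΔCA_I` the intervention arm's change in chronologic age.
Then

`PMB = (ΔHA_I − ΔHA_C) / (ΔCA_I − ΔHA_C) × 100%`.

The denominator is the room between the control trajectory and the
optimal slope-1 trajectory; the numerator is how much of that room the
intervention actually closed. The metric is invariant to the time unit
used, provided all three deltas share it. Values below 0% (harm) and
above 100% (growth faster than the skeletal-age expectation) are
mathematically possible; they are returned unclamped with
`plausible = FALSE`, since a PMB at or beyond 100% from a short
nutrition-specific intervention is a plausibility flag for the trial
itself rather than a valid effect size.

## The lookup and its edge rules

`age_at_median()` finds the table age whose median is nearest the
observed mean, on the reference's native daily grid. There is no
interpolation by default — the standard's 1-day resolution is the
method's resolution — but `interpolate = TRUE` returns the linearly
interpolated fractional day for users who want it. Exact ties between
two neighbouring days break toward the younger age.

Two edge rules matter in faltered populations:

* **Underflow.** A mean stature below the day-0 median cannot be assigned
  a height-age by a 0–5 y table; severely faltered cohorts can reach this
  state because faltering has a prenatal onset. The lookup raises an
  explicit error rather than clamping to age 0. A tolerance of half the
  first median step (and, symmetrically, half the last step at the top of
  the table) absorbs rounding at the boundaries.
* **Mode.** The standard tabulates recumbent length below 731 days and
  standing height at and above, with a systematic offset of about 0.7 cm
  between the two ways of measuring the same child. Before any lookup the
  whole median column is harmonized to the measurement's mode
  (`harmonize_mode()`): length medians lose 0.7 cm when the target is
  height, height medians gain 0.7 cm when the target is length; only the
  medians move, `S` is untouched. This is decisive for groups measured
  standing at about 2 years whose height-age falls below 731 days — on a
  reference with slope 0.1 cm/d the adjustment ages the lookup by exactly
  7 days. When the mode is not declared, it is resolved from the group's
  mean age by a hard two-year rule (`resolve_mode()`: ≥ 731 d means
  standing height / HAZ majority).

Sex-combined analyses use a sex-weighted mean of the LMS parameters
themselves (`combine_sexes()`, weights from the group's proportion of
females, 0.5 when unreported) rather than averaging z-scores, so one
combined table serves all lookups for a trial.

## CI propagation

* A reported 95% CI on a mean (stature or z) is pushed through the same
  monotone lookup as the point, giving a possibly asymmetric CI in days;
  the SE is recovered from the transformed width as
  `(upper − lower) / (2 × 1.959964)`. The bounds are kept as transformed,
  not symmetrized.
* Mean differences between arms use the independent-groups normal
  approximation `MD ± 1.959964 √(se_a² + se_b²)`.
* A within-arm change in height-age uses
  `√(se_b² + se_e² − 2ρ se_b se_e)`; the baseline–endline correlation ρ
  of the two *group means* defaults to 0 and is exposed as a parameter.
  For repeated measures on the same children ρ is typically positive,
  which would shrink this SE, so the default is the wider choice.
* The PMB CI substitutes the bounds of the between-arm `ΔHA` MD CI into
  the numerator while holding the denominator fixed; the denominator's
  own sampling uncertainty is deliberately not propagated, which keeps
  the CI interpretable as a rescaled MD CI.

## The synthetic-data generator

`make_reference()` builds a daily two-sex `L = 1` standard with median
`M(t) = M0 + a·t + b(1 − e^{−kt})` — velocity starts at `a + bk` and
decays to `a`, the fast-then-slowing shape of early childhood — plus a
constant coefficient of variation, a male–female offset, and optionally
the 0.7 cm length-to-height discontinuity at 731 days. The defaults
(`M0 = 49.1` cm, `a = 0.025` cm/d, `b = 21` cm, `k = 0.004` /d,
`S = 0.035`, offset 0.8 cm, span 0–1856 d) were chosen once to match the
scale of the 0–5 y standard: about 49 cm at birth, about 87 cm at 2 y,
early velocity about 0.11 cm/d.

`simulate_cohort()` draws ages uniformly in a window and z-scores
`Normal(μ_z, σ_z)`, setting each child's stature on the LMS model.
`simulate_trial()` inverts the PMB definition: both arms share a baseline
height-age `h0` (default `r_c` times the baseline age); over `ΔCA` days
the control arm's height-age advances by `r_c·ΔCA` and the intervention
arm's by `(r_c + p(1 − r_c))·ΔCA`, so the true PMB is exactly `100p`.
Arm means sit on the harmonized median at the target height-age, with
optional sampling noise of SE `σ_z S(t) M(t)/√n` on the stature scale.
Trial defaults — 500 children per arm, baseline at 365 d, a 180-day
observation window, `r_c = 0.5`, `σ_z = 1` — describe an infant-feeding
trial in a severely faltered population (the default `h0 = r_c × 365`
baseline corresponds to a mean z near −3.8 under the default reference;
pass a larger `baseline_height_age_days` for milder cohorts) and are the
conditions under which the recovery properties below are stated.

What the generator does *not* emulate: within-arm age heterogeneity at a
summary timepoint (arms are placed directly on the reference), secular
or seasonal velocity changes, measurement error distinct from biological
dispersion, attrition, and cluster designs. Passing tests therefore show
that the estimators recover the generative truth of this minimal model,
not that real trials are free of those complications.

## Numerical behaviour worth knowing

* **Quantization.** Nearest-day lookups quantize each height-age to 1 d,
  so a PMB built from four lookups moves in steps of roughly
  `100 × 1/(ΔCA − ΔHA_C)` percentage points (about 1.1 pp for the default
  trial). Noise-free simulated trials recover the true PMB to within that
  resolution; noisy ones at 500/arm land within a few points.
* **Jensen bias of the individual-level path.** Averaging per-child
  height-ages applies the nonlinear inverse-median transform before the
  mean, so it exceeds the mean-stature-derived height-age by roughly
  `½ f''(ȳ) Var(y)` with `f = M^{-1}`. On the default reference this is
  under 1 d for infancy cohorts but grows to several days by 2 y, which
  is one more reason the mean-stature path over a narrow age window is
  the preferred derivation; the mean-z and mean-stature paths, by
  contrast, share one lookup and agree exactly.
* **Determinism.** All simulation functions take an explicit seed;
  identical inputs give byte-identical pipeline output.

## Pilot-study conventions in the pipeline

`run_reexpression()` applies, and logs once per record, the conventions
used when re-analysing published summaries: a missing mean age is taken
to equal the scheduled measurement timing; a missing sex ratio is taken
as equal; an undeclared mode is resolved by the two-year rule. Month
ages are converted at 30.4375 d/mo at the I/O boundary only. A record
set must carry an explicit age (scheduled or mean) per timepoint —
the pipeline does not infer a follow-up age by adding a nominal
follow-up length to baseline, because reports differ in whether such
schedules are anchored at enrolment or at birth; supply the age.

When a baseline height-age cannot be derived — an intervention starting
at birth typically back-calculates a baseline mean below the day-0
median — the PMB for that contrast is reported `NA` with the reason, and
the end-line mean differences are still produced. A control arm whose
height-age change reaches the optimal rate makes the PMB denominator
non-positive and is likewise reported as a degenerate-control failure
rather than a number.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated
data: exhaustive inversion over all 1 857 ages of a full synthetic
standard, round-trip grids over all ages × 17 z-values, cohorts of
1 000–10 000 children, and six simulated trials at 500/arm. The full
suite completes in a few seconds on a single core.

## Known limitations

* 0–5 y, `L = 1` references only; no support for other anthropometric
  indices, for ages beyond the table, or for stitching references.
* Height-age is undefined below the day-0 median: severely faltered
  groups can be unanalysable at baseline, exactly the situation flagged
  by the `NA` pattern above.
* The PMB needs summaries at both ends of the observation period, a
  stricter data requirement than an end-line MD.
* No meta-analytic pooling, multiplicity handling, or multi-arm omnibus
  testing; each intervention arm is contrasted with the control arm
  separately.
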