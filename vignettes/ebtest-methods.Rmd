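---
title: "Estimating VO2max from the two-stage submaximal cycle test: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating VO2max from the two-stage submaximal cycle test: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebtest)
```

## The test and the estimation problem

Maximal oxygen uptake (VO2max) is the standard index of cardiorespiratory
fitness, but measuring it directly requires an exhaustive maximal test with
indirect calorimetry. The Ekblom-Bak submaximal cycle test estimates it from
two four-minute stages on a friction-braked ergometer: a fixed *standard*
stage of 0.5 kp at 60 rpm (about 30 W; `kp_rpm_to_watts(0.5, 60)` = 29.43 W
with the Monark convention of 6 m flywheel travel per revolution and
1 W = 6.116 kpm/min) followed directly by a higher, individually chosen
stage. Steady-state heart rate at each stage is the mean of the readings at
3:15, 3:30, 3:45 and 4:00 min (`steady_state_hr()`).

The central predictor is the heart-rate cost of power,
$\Delta HR/\Delta PO = (HR_{high} - HR_{std}) / (PO_{high} - PO_{std})$
in bpm/W: a fit individual needs a smaller heart-rate increase to absorb an
extra watt. The revised, sex-specific prediction equations are log-linear,

$$\ln \widehat{VO}_2max = b_0 + b_1\,\mathrm{age} + b_2\,\frac{\Delta HR}{\Delta PO} + b_3\,\Delta PO + b_4\,HR_{std},$$

with the published coefficients stored verbatim to their full printed
precision (see `eb_coefficients()`): men
$(2.04900, -0.00858, -0.90742, 0.00178, -0.00290)$ and women
$(1.84390, -0.00673, -0.62578, 0.00175, -0.00471)$. The log scale keeps
estimates strictly positive and stops the linear extrapolation blowing up at
either end of the fitness range. $\Delta PO$ enters in watts: all work rates
in the source material are quoted in watts, and the coefficient magnitudes
(about 0.0018 per unit) are only physiologically sensible on that scale.
The original 2012 comparator is a single pooled linear equation,
$\widehat{VO}_2max = 4.98196 - 2.88618\,\Delta HR/\Delta PO +
0.65015\,\mathrm{sex} - 0.01712\,\mathrm{age}$ (women 0, men 1).

These published coefficients are *never* refitted by the package: the
estimators use them exactly as printed. The model-development machinery
below exists to reproduce the procedure and to verify, generatively, that
the machinery is correct.

## Validity ranges and gating policy

The sex-specific equations were developed on ages 20-86 years and measured
VO2max of 1.33-3.94 L/min (women) and 1.67-5.97 L/min (men); the 2012
equation on ages 21-65 and 1.56-3.73 / 2.75-4.49 L/min. Inputs or
predictions outside these spans set `in_valid_range = FALSE` and append a
warning string, but are never rejected -- applicability is advisory for the
regression equations, and decimal ages are accepted. The one hard gate is
the Astrand comparator's nomogram window: a high-stage heart rate outside
120-170 bpm is not interpretable on the nomogram at all, so
`astrand_estimate()` raises a not-applicable error (or returns `NA` per
record under `on_invalid = "na"` when sweeping a cohort, mirroring how such
tests are excluded from comparison analyses).

## The Astrand comparator and the shipped table

The Astrand method reads an uncorrected VO2max from a sex-specific
(work rate, heart rate) table and multiplies by an age-correction factor.
The package interpolates bilinearly over the grid and linearly between
tabulated ages, and is agnostic to the grid supplied. The shipped table is
a **synthetic reconstruction**: the original nomogram charts are not
reproduced here, so the file `astrand_table_synthetic.csv` is generated
from the nomogram's underlying linear HR-%VO2max model (men anchored at
HRmax 195 / HR intercept 61 bpm, women 198 / 72 bpm; oxygen cost of
cycling 2 mL per kpm plus a 0.3 L/min baseline). Structural guarantees --
exactness at grid nodes, interpolates bounded by neighbouring nodes -- hold
for any table in the documented format; numeric agreement with the original
charts is only as good as the table supplied, and users who need faithful
Astrand values should substitute a transcription of the original tables via
`astrand_table(nomogram_path =, correction_path =)`.

## Agreement statistics and their conventions

`agreement_report()` and `stratified_report()` compute the method-comparison
set against measured values. Where the classical definitions leave choices
open, the package fixes them as follows and exposes them as arguments where
reasonable:

* **Sign of the difference.** `difference = estimated - measured`, so
  overestimation is positive. This is the single convention used by the
  paired t, Bland-Altman and error-versus-level statistics; it makes the
  familiar pattern "fit individuals are underestimated" print as a negative
  mean difference in the top fitness quartile.
* **Coefficient of variation.** `100 * SD(differences) / level`, where the
  level is the mean of the two group means (equivalently the grand mean of
  all measured and estimated values) -- the standard method-comparison
  reading -- and the SD uses the n-1 denominator. Both are the defaults of
  `cv_percent()`; the SD denominator is switchable.
* **SEE and adjusted R²** come from the OLS regression of measured on
  estimated (`see_and_r2()`): SEE is the residual standard error, R² carries
  the one-predictor adjustment. Note this measures linear association, not
  identity -- `measured = 2 * estimated` fits perfectly -- which is exactly
  why the mean difference and limits of agreement are reported alongside.
* **Limits of agreement** are `mean(diff) ± 1.96 * SD(diff)`;
  `bland_altman()` also returns the per-pair (mean, difference) plotting
  coordinates.
* **Quartiles.** Fitness strata use the published sex-specific cut-points of
  measured VO2max (absolute: women 2.14/2.59/2.93, men 3.07/3.75/4.33 L/min;
  relative: women 32.5/40.2/47.4, men 37.5/47.6/54.8 mL/kg/min). The printed
  ranges overlap at their boundaries, so a boundary value is assigned to the
  higher quartile; assignment is on *measured* VO2max (stratifying by actual
  fitness). Age bands default to <35, 35-49, 50-64, >=65 years.
* **Multiple testing.** None: raw p-values are reported.
* Strata with fewer than two pairs are reported as `NA` with their count.

The useful corollary `prediction_halfwidth(cv, vo2max) = 1.96 * cv * vo2max`
turns a validation CV into the half-width of the 95% individual prediction
band: at CV 8.4% a true 3.0 L/min is predicted within ±0.49 L/min.

## Model development: forward selection

`forward_select()` implements classical forward stepwise OLS with the
"probability of F" criterion: at each step the candidate with the smallest
partial-F p-value (equivalently the squared-t p-value of its coefficient in
the trial fit -- packages differ on the bookkeeping, this is the classical
reading) enters if p < `p_enter` (default 0.05); after each entry any
included variable with p > `p_remove` (default 0.10) leaves. The response
for the prediction-equation refit (`fit_eb_model()`) is ln VO2max.
Perfectly collinear candidates raise a degenerate-design error naming the
column. Confidence intervals are t-based with residual degrees of freedom.
`interaction_screen()` fits the pooled two-sex model with sex-by-HR and
sex-by-(delta HR / delta PO) terms and recommends splitting by sex when
either interaction is significant -- the screen that motivates sex-specific
equations. `tolerance_check()` reports 1 - R² of each predictor on the
others and flags values at or below 0.2 as likely multicollinearity.

## The synthetic-cohort generator

Real validation cohorts are human data and are not distributable, so the
package ships a generator (`cohort_spec()`, `generate_cohort()`) with two
modes.

**exact_model** draws covariates uniformly over the design space (age over
20-86 years; delta HR / delta PO 0.25-1.0 bpm/W; delta PO 60-220 W; standard
stage HR 70-115 bpm), sets ln VO2max exactly from the published sex equation
and adds Gaussian ln-scale noise of SD `ln_noise_sd`. With noise 0 the
estimators recover the generative truth to machine precision (the
round-trip identity behind the coefficient-recovery checks); the uniform
covariates give a well-conditioned design for those refits. The default
noise SD of 0.085 is a *calibration*, not a literature value: it is the
ln-scale residual level at which end-to-end validation of the equations
yields a coefficient of variation of about 8-9%, matching the precision
reported for cohorts of this composition. No published ln-scale residual SD
exists to use instead.

**physiologic** mode emulates the study population: per sex, age, body mass
and VO2max are drawn from truncated normals matching the published cohort
(men 48.3 ± 15.7 y, 80.7 ± 9.0 kg, 3.73 ± 0.86 L/min; women 46.1 ± 16.8 y,
63.7 ± 8.5 kg, 2.55 ± 0.58 L/min; ages truncated to 20-86 and VO2max to the
development ranges, via inverse-CDF sampling). Maximal HR follows
208 - 0.7 x age (a standard published estimator; SD 8 bpm) -- the source
cohort description gives no formula. Each individual gets a linear HR-VO2
line through (resting VO2, resting HR) and (VO2max, HRmax); resting HR is
65 ± 8 bpm, a configurable default with no cohort basis. Stage heart rates
are read off the line at the oxygen cost of the work rate
(0.0108 L/min per W plus 0.007 L/min per kg, the standard leg-ergometry
cost), with 2 bpm noise; the high work rate targets 75% of maximal HR, a
stand-in for the protocol's "perceived exertion of about 14", rounded to
5 W. Records violating the protocol invariants are rejection-sampled with a
hard cap of 1000 attempts (then an error, rather than silently distorting
the distributions).

What the generator does *not* emulate: day-to-day biological variation,
measurement error of the maximal treadmill test, medication effects,
non-linearity of the HR-VO2 relationship near maximal effort, and the
recruitment biases of a volunteer sample. Passing tests on these cohorts
therefore demonstrate that the implementation is faithful and
well-calibrated, not that the equations are valid in any particular human
population -- the published cross-validation carries that claim.

## Numerical and testing choices

Problem sizes are chosen for tight, fast tests: coefficient-recovery refits
use noise-free cohorts of a few hundred records (recovery is exact to well
below 1e-6 regardless); the calibration check uses 200 records; oracle
equivalence of the agreement statistics is checked against hand-rolled
normal-equation and explicit-rank implementations on 1000 random 10-element
samples; the forward-selection false-entry rate is checked against its
nominal level over 500 replicates with a binomial tolerance; the null
interaction screen over 200 replicates against its theoretical
$0.95^2$ pooled rate. Determinism: the generator seeds R's RNG locally and
restores the caller's state, so the same spec and seed give byte-identical
cohorts.

Degenerate inputs are handled explicitly rather than left to downstream
`NaN`s: zero-variance differences give p = 1 (identical vectors) or p = 0
(constant nonzero shift) with a note; a constant estimated vector is a
degenerate-regression error; constant differences make the error-level rank
correlation undefined (`NA` with a note); quartile cut-points must strictly
increase.

## Limitations

The shipped Astrand table is a model-based reconstruction (above), so
Astrand comparator *values* should not be quoted against the original
charts without substituting a faithful table. The published validation
tables themselves (model-group CV 8.7%, SEE 0.28 L/min, adjusted R² 0.91)
are not reproducible from this package because the underlying human data
are not distributable; the package's claims are the generative and
structural guarantees its tests compute. The equations assume an intact
HR-work relationship: beta blockade or other chronotropic medication breaks
the premise, and no clinical-population support is attempted.
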