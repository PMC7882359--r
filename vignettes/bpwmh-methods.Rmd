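---
title: "Methods: blood pressure and white matter hyperintensity burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blood pressure and white matter hyperintensity burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

White matter hyperintensities (WMH) are FLAIR-bright lesions of cerebral
white matter, a core imaging marker of small vessel disease and a risk
factor for stroke and dementia. Their burden rises with age and with
blood pressure (BP), but two questions are hard to answer from a single
clinic measurement: *which exposure window matters* (concurrent vs. past,
midlife BP), and *which pressure component* (systolic, SBP, vs.
diastolic, DBP). A single BP reading is a noisy proxy for a person's
long-term pressure, so naive regressions of WMH on one measurement are
attenuated — the classical *regression dilution bias*.

`bpwmh` implements the full analysis chain for a UK-Biobank-shaped
longitudinal cohort: a baseline visit with BP, a follow-up (imaging)
visit roughly nine years later with BP and quantitative MRI volumes.

## Outcome definition

The outcome is **WMH load**: WMH volume divided by total white matter
volume, a proportion strictly inside (0, 1); a sensitivity variant
divides by total brain volume (grey + white + CSF). Because the load
distribution is heavily right-skewed (typical medians near 0.005 with a
range spanning four orders of magnitude), all linear modelling is done on
the **logit** of the load, which normalizes the distribution and
stabilizes variance. We never clamp loads at the boundary: a load of 0 or
1 is treated as a data fault and raises an error, since the smallest
plausible observed loads are interior (of order 1e-5).

At small loads `logit(p) = log(p) + O(p)`, so a coefficient `b` per mmHg
on the logit scale corresponds to a multiplicative load change of
`exp(b)` per mmHg; effects are reported per 10 mmHg SBP and per 5 mmHg
DBP, the field's conventional units.

## BP harmonization and category assignments

Each visit can carry up to two SBP/DBP readings from each of three
sources. The harmonized visit BP prefers the automated sphygmomanometer,
then manual readings, then pulse-wave-analysis (PWA) estimates, and
averages the available readings of the chosen source within the visit. A
source counts as present only if it has at least one SBP *and* one DBP
reading; a single available reading is used as-is (this discards less
data than requiring pairs; the choice is visible in the audit and can be
probed with the `exclude_pwa` sensitivity flag).

Categories use standard clinic thresholds with **left-closed** intervals
(a boundary value belongs to the upper band): SBP <120, 120–130, 130–140,
≥140 mmHg; DBP <70, 70–80, 80–90, ≥90 mmHg; baseline age groups <50,
50–60, ≥60 years and follow-up age groups <60, 60–70, ≥70 years.

Eligibility filters run in a fixed, audited order: missing WMH volume →
exclusion diagnosis flag → missing follow-up BP → missing baseline BP
(longitudinal set only). The audit table reports the count removed at
each step, so any alternative accounting of the same cohort can be
reconciled against ours explicitly. The cross-sectional set stops one
filter earlier and is therefore always a superset of the longitudinal
set. The follow-up interval is exact days between visit dates divided by
365.25.

## Association models

Three adjustment tiers mirror standard epidemiological practice:

* **unadjusted** — each exposure alone;
* **age-sex adjusted** — each exposure plus age and sex;
* **fully adjusted** — SBP and DBP entered jointly, plus age, sex,
  arterial stiffness index (ASI), smoking (never/ex/active indicators),
  diabetes, BP source, and assessment centre; longitudinal ("past")
  models additionally adjust for the between-visit interval.

Fits are ordinary least squares with normal-theory (t quantile) 95%
confidence intervals, complete-case on the model's variables. For
standardized coefficients, the outcome and continuous predictors are
z-scored on the fitted sample; binary and categorical indicators are
*not* z-scored, so their coefficients read as outcome-SDs per level
(z-scoring indicators would change sign conventions and units without
adding interpretability). Centre and BP source enter as unordered factors
with the most frequent level as reference; their choice affects only the
intercept. Stratified fits (age group, sex, follow-up-duration median
split) remove the stratifying variable from the adjustment set and skip
strata too small to support the design, with a warning. Sex interactions
add an exposure-by-sex product term to the full model.

Bootstrap intervals are deliberately *not* used here; they are reserved
for the usual-BP analysis where no closed-form interval exists for the
two-stage median-ratio pipeline.

## Population attributable fraction

The population burden of severe WMH is summarized as the fraction of
top-decile WMH load attributable to SBP >120 mmHg or DBP >70 mmHg
(strict thresholds, tested at the boundary). The decile is computed
within the analysis sample by linear interpolation of order statistics
(the default sample quantile), with strict exceedance so exact ties are
not flagged.

No closed-form "fully adjusted PAF" exists, so we chose logistic
**g-computation** (model-based standardization): fit a logistic model of
the top-decile flag on the exposure indicator plus the adjustment set,
then contrast the mean observed risk with the mean predicted risk when
everyone is set to unexposed:

`PAF = (p_obs - p_cf) / p_obs`.

With an empty adjustment set this reduces *exactly* to Levin's classical
formula `pe (RR - 1) / (1 + pe (RR - 1))`, which the tests verify to
1e-10 on enumerated 2×2 populations. The estimator sits behind the
`estimate_paf()` contract and could be swapped (e.g. for doubly robust
standardization) without touching callers. Separation or non-convergence
of the logistic fit raises an error rather than returning an
extrapolated fraction. Note that the crude (unadjusted) PAF isolates the
prevalence-driven burden comparison between SBP and DBP; the adjusted
PAF conditions on age, which absorbs much of the SBP exposure contrast
and is therefore substantially noisier at moderate sample sizes.

## The usual-BP analysis (regression dilution correction)

The dilution correction follows the classical usual-exposure design:

1. stratify participants by baseline age group × baseline BP band;
2. estimate each stratum's **usual BP** as the mean *follow-up* BP of
   its members — because strata were defined at baseline, the follow-up
   mean shrinks toward the population mean exactly as the members'
   long-term pressures do;
3. take the median WMH load per stratum as a ratio to the reference
   stratum (lowest band within the youngest age group — "normotensive
   people in the youngest age group");
4. regress the log median ratios on usual BP, per age group and across
   all strata ("overall"), unweighted (equal-stratum weighting is the
   primary analysis; size-weighting is available behind a flag).

Confidence intervals come from a non-parametric **percentile bootstrap**:
participants are resampled with replacement and the *entire* pipeline —
strata, usual BP, medians, regression — is recomputed each replicate.
Percentile intervals are the simplest method consistent with a plain
non-parametric bootstrap; replicates whose reference stratum comes up
empty are redrawn and counted, and the run fails if more than 10% of
replicates cannot produce an overall slope. Given the seed the analysis
is fully deterministic.

Design choices left open by the general method, fixed here:

* SBP and DBP are analysed in separate stratifications, not jointly.
* The "overall" fit pools all strata across age groups rather than
  refitting on collapsed strata; the within-age-group fits are reported
  alongside.
* Medicated participants are included by default (`exclude_medicated`
  provides the sensitivity variant).
* Strata below `min_n = 20` members are dropped (except the reference,
  which must exist); 20 keeps stratum medians stable without discarding
  informative cells.

## Treatment categories

BP severity for the hypertension/treatment analysis grades both
pressures and takes the **maximum** severity — an "or" rule: SBP <120
*and* DBP <70 is the lowest category; SBP 120–130 *or* DBP 70–80 the
next; then SBP 130–140 or DBP 80–90; then SBP ≥140 or DBP ≥90. Severity
is crossed with the antihypertensive medication flag, and every category
is contrasted against unmedicated participants in the lowest category
with a linear model adjusted for decade of age (`floor(age/10)`), sex,
ASI, smoking, diabetes, centre, and the interval (longitudinal). The
model pools age groups with the decade covariate; per-age-group medians
and interquartile ranges are emitted for plotting.

## The synthetic cohort generator

No deposited individual-level data exist for this design (the source
cohort is access-restricted), so the generator is a first-class module:
it defines the study conditions under which every estimator is tested,
with known ground truth.

* **Latent BP.** Participant-level latent (SBP, DBP) are bivariate
  normal (default means 134.8/81.4 mmHg at baseline, SDs 15.7/7.9,
  correlation 0.6), shifted at follow-up (+3.5/−3.7 mmHg) and tracking
  across visits at correlation 0.7. Latent BP rises with age (0.5/0.1
  mmHg per year, centred), making age a confounder of the marginal
  dose-response, as in real cohorts.
* **Measurement.** Each visit draws a source (automated 90%, manual 8%,
  PWA 2%) and up to two readings per pressure; each reading adds
  independent normal noise (defaults 8 mmHg SBP, 6 mmHg DBP). Published
  sources do not report within-person reading variability, so these
  defaults are *assumptions*, chosen once as typical clinic-reading
  variability — not calibrated values.
* **Outcome.** `logit(load)` is linear in the latent *untreated*
  follow-up pressures (defaults `log(1.041)/10` per mmHg SBP and
  `log(1.031)/5` per mmHg DBP — the magnitudes of published fully
  adjusted per-unit effects, used as the joint effects of the two
  correlated pressures), plus centred covariate effects and normal noise
  (SD 1.1 on the logit scale, wide enough to reproduce a four-decade
  load range around a median of 0.0052).
* **Medication.** Antihypertensive treatment is assigned with
  probability increasing in latent SBP (intercept calibrated on the
  sample so prevalence hits 14.6% at baseline and 26.1% at follow-up);
  treatment lowers *measured* BP by 10/6 mmHg while WMH keeps tracking
  the untreated latent pressure. This is confounding by indication in
  its simplest form and reproduces the elevated WMH of treated people at
  normotensive measured values.
* **Determinism.** A single master seed; every stage derives its own
  sub-stream from a hash of the stage name, so adding a stage never
  perturbs earlier draws, and equal seeds give byte-identical cohorts.

What the generator deliberately does **not** emulate: voxel-level
imaging, medication initiation dynamics beyond a static per-visit flag,
realistic diagnosis coding (a single boolean exclusion flag stands in),
non-normal BP tails, and cohort attrition mechanisms beyond independent
field-level missingness. Passing tests therefore demonstrate estimator
correctness under a plausible data-generating process, not fidelity of
any particular real-world dataset.

## Numerical choices and degenerate inputs

* Quantiles everywhere are type-7 (linear interpolation of order
  statistics).
* `logit()` errors outside (0, 1); no epsilon clamping anywhere.
* Truncated normal draws (follow-up interval) use the inverse-CDF method
  so they stay deterministic under the stage's RNG stream.
* Logistic fits for the PAF use a tightened IRLS tolerance (1e-12) so
  the unadjusted estimator matches Levin's closed form to 1e-10.
* Rank-deficient linear designs raise an error naming the collinear
  columns; constant factors (e.g. a single centre) are dropped from the
  adjustment set before fitting.
* Zero-variance variables cannot be standardized and raise an error
  naming the variable.

## Problem sizes used by the test suite

The simulation-based checks use cohort sizes chosen to keep Monte-Carlo
error well below the effects being tested while remaining quick on one
CPU: bias checks at n = 6000 over 12 seeds; bootstrap-coverage
calibration on 200 cohorts of n = 5000 with 200 replicates each;
usual-BP CI recovery on 100 cohorts of n = 20 000 with 200 replicates;
qualitative population-pattern checks on single cohorts of n = 20 000.
The reported analyses in `scripts/acceptance.R` use n = 20 000 and 500
bootstrap replicates.

## Known limitations

* The usual-BP slope estimator carries a small (about 2%) downward bias
  relative to the generator's latent slope, from two second-order
  effects: within-stratum medians of a skewed latent distribution sit
  slightly off the means, and the logit link is not exactly the log link
  at non-negligible loads. Both are far below the sampling noise at the
  tested sizes.
* The fully adjusted linear model estimates *measured-BP* coefficients;
  with measurement noise on, these are attenuated relative to the latent
  effects by design — that attenuation is the phenomenon the usual-BP
  module corrects, and the test suite asserts the direction of the gap
  rather than pretending it away.
* Printed summary tables round to two decimals, so arithmetic identities
  across published means are asserted only to printed precision.
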