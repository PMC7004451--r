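---
title: "Estimating joint PM2.5 and extreme-heat effects in early pregnancy"
author: "heatpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating joint PM2.5 and extreme-heat effects in early pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Congenital heart defects (CHDs) form during a short embryonic window —
postconceptional weeks 3–8, when the heart tube loops and septates. Ambient
fine particulate matter (PM2.5) and extreme heat are both candidate risk
factors during this window, and they co-occur: heat episodes change both
pollution chemistry and maternal physiology, so the interesting question is
not each exposure alone but whether heat *modifies* the PM2.5 association.
`heatpm` implements the full analysis chain for that question in a
population-based case–control design: exposure construction from daily
monitor and weather series, and interaction estimation on both the
multiplicative and the additive scale. Because the motivating study
populations are restricted-access, the package ships a synthetic-data module
that emulates the structure of such a study with known true effect sizes, so
every downstream stage is testable and its statistical calibration can be
demonstrated end to end.

## Exposure construction

**Critical window.** Conception is estimated from the estimated date of
delivery as `EDD − 266` days (38 postconceptional weeks, the standard
clinical term). Postconceptional day 1 is the first day after conception and
week *k* covers days `7(k−1)+1 … 7k`, so weeks 3–8 are days 15–56: a 42-day
window from `conception + 14` through `conception + 55`, both inclusive.
These conventions are stated explicitly because off-by-one-week errors are
the dominant failure mode in gestational exposure work; the invariant
`end − start + 1 = 42` is asserted in the tests for arbitrary dates. Source
data often carry EDD rather than the actual delivery date, which is why EDD
drives the default; `conception_from_delivery()` offers the
delivery-date + gestational-age reconstruction for users who prefer it.

**Linkage.** Residences (already geocoded to coordinates; geocoding is out
of scope) are linked to the nearest PM2.5 monitor by great-circle distance
(haversine, Earth radius 6371 km) subject to a 50 km cap — subjects beyond
the cap stay in the exposure table with missing PM fields and an explicit
exclusion reason — and to the nearest weather station with no cap. Distance
ties break to the lexicographically smallest site id so linkage is
deterministic. One residence per subject: residential mobility is not
modelled.

**Window averages.** The PM2.5 exposure is the arithmetic mean of available
monitor days inside the window, declared missing below `min_days = 28` of 42
days (two-thirds coverage; configurable — daily monitor series have gaps and
some coverage rule is unavoidable, but none is canonical). The humidity
confounder is operationalized the same way: the window mean of the linked
station's dew point. Dew point enters models as a single linear term; no
spline, because nothing in the design motivates a specific nonlinear form.

**Dichotomization.** Window-mean PM2.5 is cut at the 80th percentile of the
*control* distribution. The percentile is the linear-interpolation order
statistic at `h = (n−1)p + 1` (the "type 7" convention, the default of most
statistical software), used identically for the PM cut and the temperature
thresholds below so every cutoff is bit-reproducible; tests verify it
against a hand-rolled sort-and-interpolate oracle to 1e-12. Exceedance is
strict (`>`), so a value exactly at the threshold is classified low, and the
controls-only definition means adding or removing cases can never move the
threshold (also a tested invariant).

**Seasons.** Month-based: MAM spring, JJA summer, SON autumn, DJF winter,
with December assigned to the following January's winter (irrelevant to the
spring/summer analyses, fixed for determinism). Three subpopulation flags
are computed over every day of the window: at least one spring/summer day,
the entire window in spring/summer, at least one summer day.

## Extreme heat events

An extreme heat event (EHE) is a run of consecutive calendar days with daily
maximum temperature strictly above a percentile of that station's Tmax
distribution *for the season and year*: at least 2 days above the 95th
percentile (EHE95) or at least 3 days above the 90th (EHE90). Decisions the
run semantics forced:

* **Runs do not cross season boundaries.** The threshold itself is only
  defined within a season-year, so each segment is scanned independently; a
  spell straddling May 31/June 1 can yield two events or none. This is the
  only reading under which "above the threshold" is well-defined on every
  day of an event.
* **Missing days break runs** — a run cannot be certified across unobserved
  days.
* **Strict exceedance**: a day exactly at the threshold breaks a run,
  matching the percentile convention above.
* **Thresholds are per station**, each subject inheriting the thresholds of
  their linked station; computing them pooled over a study centre would be
  an alternative reading, but per-station is the one consistent with
  station-level linkage.
* A season-year with fewer than 10 observed Tmax days has an undefined
  threshold and is skipped with a warning rather than silently producing a
  percentile of noise.

A window counts as EHE-exposed if **any** event day overlaps it
(any-overlap rule): the heat is experienced on each event day, so requiring
the entire event inside the window would discard real exposure at the window
edges. Event detection is verified exactly against an exhaustive O(n²)
maximal-run oracle on hundreds of random series, including the
season-boundary and missing-day cases. Note EHE95 events need not be nested
inside EHE90 events (different percentile *and* different minimum run) — the
tests carry a counterexample rather than a false invariant.

## Interaction estimation

All models are logistic regressions for case status adjusted for maternal
age (≤19 / 20–34 / ≥35), education (<12y / ≥12y), race/ethnicity (4 groups)
and window-mean dew point; the full-population model additionally adjusts
for the any-spring/summer-day indicator. Analyses are complete-case, with
dropped-row counts reported per model — the motivating designs have little
covariate missingness and imputation would add assumptions the data cannot
check.

**Multiplicative scale.** The product-term model
`logit P(case) = α + β_pm·PM + β_ehe·EHE + β_int·PM·EHE + γ'Z` gives
stratum-specific odds ratios `OR(PM | no EHE) = exp(β_pm)` and
`OR(PM | EHE) = exp(β_pm + β_int)` (Wald CIs, the second using
`var(β_pm) + var(β_int) + 2 cov`; equivalent, as tested, to refitting with
the stratum recoded). Effect-measure modification is tested by the
likelihood-ratio test of the product term against chi-square(1), flagged at
α = 0.1 — the conventional trade of type-I error for power when probing
interactions in case–control data.

**Additive scale.** A 4-level joint variable (reference: low PM, no EHE)
yields OR10 (high PM only), OR01 (EHE only), OR11 (both), and the relative
excess risk due to interaction

> RERI = OR11 − OR10 − OR01 + 1,

which is 0 under exactly additive joint effects. The RERI reported is exact
arithmetic on the fitted ORs of the same model.

**Likelihood-based RERI interval.** The 95% interval endpoints are the RERI
values *r* at which the constrained maximum log-likelihood — maximizing over
*all* coefficients subject to `exp(β11) − exp(β10) − exp(β01) + 1 = r` —
drops `qchisq(0.95, 1)/2 = 1.9207` below the unconstrained maximum. The
constraint is eliminated by substituting
`β11 = log(r − 1 + exp(β10) + exp(β01))` (infeasible excursions get a linear
penalty), and each constrained problem is solved by BFGS with analytic
gradients, warm-started from the neighbouring solution. The search brackets
outward from the point estimate in steps of twice the delta-method SE, then
bisects until the endpoint's profile deviance matches `qchisq(0.95, 1)` to
1e-3 — a defining property the tests assert directly. Failures on a side
produce an NA bound with a diagnostic status, never a silent fall-back to
the delta interval. The delta-method interval (gradient
`(−e^{β10}, −e^{β01}, e^{β11})`) is always reported alongside as the fast
asymptotic cross-check; at large n the two agree to within 10% of interval
width (tested).

Logistic fits themselves use iteratively reweighted least squares
(`stats::glm.fit`) with relative tolerance 1e-8 and at most 100 iterations;
separation is flagged through boundary fits and coefficient norms above 15
on the log-odds scale, and every downstream consumer refuses to interpret a
non-converged fit. Empty joint-exposure cells are flagged, the model still
attempted, and the degenerate CIs left visible rather than suppressed.

## The synthetic-data module

The generator is the package's study-condition definition, not a tuning
knob:

* **Weather**: Tmax = single-sinusoid seasonal mean (base 15 °C, amplitude
  12 °C, peak mid-July — a continental mid-latitude climate) plus a
  stationary AR(1) anomaly (ρ = 0.7, innovation SD 3 °C). The AR(1)
  persistence is what makes multi-day percentile-exceedance runs occur at
  realistic rates; the lag-1 autocorrelation of generated anomalies is
  verified to ±0.05. Dew point = Tmax − 8 °C + noise, so it co-varies with
  heat the way humidity does. A single sinusoid is the simplest curve that
  yields sensible season-specific percentile thresholds.
* **PM2.5**: log-normal daily values (log-SD 0.4) about a seasonal mean
  (12 ± 3 µg/m³), 10% of days missing at random — typical urban magnitudes
  and monitor-gap behaviour. Under the default geometry this puts the
  control 80th-percentile cut near 16 µg/m³.
* **Subjects**: residences uniform over a ~2°×2° study region containing a
  handful of stations and monitors, so a realistic minority of subjects
  fall outside the 50-km monitor cap and exercise the exclusion path; EDDs
  uniform over several years so conception dates cover all twelve months;
  covariates drawn independently from marginals resembling a large US birth
  cohort (75% ages 20–34, 80% ≥12y education, 60% NH-white). Covariates are
  independent of exposure by default so confounding behaviour can be
  switched on deliberately (via `covariate_betas` plus exposure-dependent
  residence assignment) rather than lurking in every test.
* **Outcomes**: Bernoulli draws from the logistic model of `true_model()`,
  which records its implied joint ORs and RERI. Case–control sampling is
  outcome-only (unmatched population-based design), which biases only the
  intercept, so exposure ORs are preserved — the property the whole
  case–control machinery rests on, and the tests confirm.

What the generator does *not* emulate: real monitor-network geometry,
spatial correlation between nearby monitors, within-window residential
mobility, exposure-measurement error from using ambient concentrations, or
outcome misclassification. Passing tests therefore demonstrate the
*statistical machinery* is correct and calibrated under the stated
generating model — not that any particular epidemiologic estimate from real
data is unbiased.

## Calibration studies

Three simulation studies define the package's statistical guarantees, run
at these sizes by the test suite and the acceptance script:

1. **LRT calibration**: 1,000 case–control replicates (1,500/1,500) from a
   main-effects-only model (ORs 1.3 for PM, 1.2 for EHE, modest covariate
   effects, baseline prevalence 8%); the empirical rejection rate at
   α = 0.1 must sit within the binomial 99% band (±0.025) of the nominal
   level.
2. **Profile-CI coverage**: 500 replicates (2,000/2,000) from a joint model
   with (OR10, OR01, OR11) = (1.5, 1.3, 2.3), i.e. true RERI = 0.5;
   empirical 95% coverage within ±0.03.
3. **Recovery**: one 200,000-pregnancy cohort with OR(PM | no EHE) = 1.0 and
   OR(PM | EHE) = 1.6; fitted stratum ORs within ±0.1 and RERI within ±0.15
   of truth.

`analysis/04_calibration.R` reruns compact versions of the same studies
interactively. The narrative pipeline in `analysis/01–03` simulates a
25,000-pregnancy cohort (seed 42), samples 1,000 cases and 1,500 controls,
and carries them through exposure assignment and the full
4-filter × 2-definition model grid.

## Known limitations

* The conception-date formula, percentile convention and monitor-coverage
  rule are stated conventions, not estimable from data; users whose source
  studies used different ones should set them explicitly.
* The profile-likelihood interval is a generic likelihood-based
  construction; other software lineages implement "likelihood-based RERI
  CIs" with different parameterizations that can differ in small samples.
* Stratified model grids multiply comparisons; the package deliberately
  applies no multiplicity adjustment, leaving that interpretive burden with
  the analyst.
* Very sparse joint cells (rare exposures in small subpopulations) push the
  4-level model toward separation; the package flags rather than fixes
  this — penalized likelihood would be the natural extension.
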