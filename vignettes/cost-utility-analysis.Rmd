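---
title: "Trial-based cost-utility analysis with ceatk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-based cost-utility analysis with ceatk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatk)
```

ceatk implements the economic-evaluation pipeline that runs alongside a
two-arm randomised trial: scoring EQ-5D-3L health states to utilities,
computing QALYs, costing resource use and a micro-costed psychotherapy
intervention, multiply imputing incomplete follow-up data, and estimating
adjusted incremental costs and effects with a non-parametric bootstrap
nested inside the imputations. This vignette explains the models and the
choices behind them; the README shows the quick path through the code.

## The estimand and the estimator

For intervention (I) versus control (C) the quantities of interest are the
adjusted mean differences in total cost, $\Delta C$, and effect,
$\Delta E$ (QALYs in the primary analysis, depression-scale points in a
secondary one), over a stated horizon. Their ratio is the incremental
cost-effectiveness ratio
$\mathrm{ICER} = \Delta C / \Delta E$, and for a willingness-to-pay
threshold $\lambda$ the net monetary benefit is
$\mathrm{NMB}(\lambda) = \lambda\,\Delta E - \Delta C$. The
cost-effectiveness acceptability curve (CEAC) reports
$P(\mathrm{NMB}(\lambda) > 0)$ over a grid of thresholds, estimated as the
fraction of bootstrap replicates with positive NMB.

Both differences come from least-squares regressions of the outcome on the
arm indicator plus pre-specified baseline covariates (age, sex, baseline
depression score) and the baseline values of the variables of interest
(baseline cost, baseline utility). Adjustment happens only in this
regression stage: QALYs are not themselves re-centred on baseline utility.
Cost data are strongly right-skewed, so uncertainty comes from a
non-parametric bootstrap rather than normal theory: participants are
resampled with replacement **stratified by arm with arm sizes fixed**,
preserving the randomisation ratio, and both regressions are refit in
every resample (so adjustment uncertainty propagates). With `m` imputed
datasets and `B` resamples per dataset the pooled cloud has `m × B`
replicates; the study configuration of `B = 1000` and `m = 30` gives the
familiar 30 000-replicate cloud.

Point estimates and their standard errors are pooled across imputations by
the usual combining rules (`rubin_pool()`); interval estimates are
percentiles of the pooled cloud, treating all `m × B` replicates as one
distribution. Both surfaces are exposed because pooling conventions for
bootstrap-within-imputation vary across practice.

## Utilities and QALYs

`eq5d_utility()` scores five-digit EQ-5D-3L profiles under an additive
tariff: full health (11111) is exactly 1; any other state subtracts a
constant, a decrement for each dimension at level 2 or 3, and one extra
decrement if any dimension is at level 3. The packaged default
(`uk_eq5d_tariff()`) is the UK general-population time-trade-off set,
under which the worst state 33333 scores −0.594. Any tariff obeying the
same contract can be supplied; the coefficients are configuration, not
code.

`qaly_auc()` integrates the utility trajectory by the trapezoidal rule —
linear interpolation between assessment waves — and divides by 12 to turn
month-scale time into years. Two deliberate restrictions: the horizon must
coincide with an assessment time (no extrapolation), and a missing state
inside the horizon yields a missing QALY (no carry-forward — missing
outcomes are the imputation stage's job).

## Costing

Health and social care use is costed by multiplying reported contacts by
unit costs (`cost_services()`); items left blank on an otherwise completed
questionnaire count as zero use, while unpriced codes are an error.
The packaged `default_unit_costs()` are plausible 2014–2015 placeholders
meant to be overridden with a local table; an uprating multiplier table
re-bases costs collected in other price years.

The intervention is the one micro-costed item. An attended individual
session costs `hourly employment cost × (1 + non-direct ratio) ×
duration`; the default ratio of 0.91 non-direct hours per direct hour
covers preparation, supervision and administration. Unattended individual
sessions cost nothing, on the argument that therapists redeploy freed
time. Group sessions are closed and run regardless of turnout, so each
session's full cost (one therapist up to groups of three, two above that;
2.5 hours by default) is divided evenly across everyone **invited**,
attending or not — `cost_group_session()` conserves the session cost to
the penny across invitees, and tests assert it. Therapy-specific training
costs are excluded by construction.

Medications are costed as a per-day cost (median dose of the modal drug in
each category) times the days of overlap between the reported start/finish
dates and the costing window, assuming full adherence. Productivity losses
(absenteeism, and presenteeism computed alongside) are valued at the
national gross average wage for participants in paid employment — the
human capital approach — and are always reported separately from the
NHS/personal-social-services total: `cost_summary()` treats perspective
separation as an invariant. The broader-perspective sensitivity scenario
adds absenteeism only; presenteeism is computed and available but not
added by default, since its inclusion is the more contested choice.

## Missing data

Analysis and imputation operate at the aggregate level: per-interval
other-care cost totals, per-interval QALY contributions, productivity
costs and depression scores (`build_analysis_table()`). The intervention
cost comes from therapy records and is always observed.

`mice_impute()` is a chained-equations imputer: each incomplete variable
is regressed on the complete baseline predictors (arm, age, sex, baseline
severity, baseline utility, baseline cost, intervention cost, employment)
plus the current values of the other incomplete variables, and missing
cells are redrawn each cycle; ten cycles per dataset, `m` datasets on
independent sub-streams. Continuous variables use type-1 predictive mean
matching with five donors — imputed costs are always observed values, so
they stay non-negative and respect the skew; a Bayesian linear draw
(`"norm"`) and a logistic draw for binaries (`"logreg"`) are available by
configuration. The exact predictor set of any original analysis is rarely
printed, so it is fully configurable; the default above is a documented
choice. Observed cells are never altered, and tests assert this cell by
cell.

The number of imputations follows the rule of setting `m` to the
percentage of participants with incomplete service-use information
(`choose_m()`, half-up rounding, floor of 2 so pooling is always
defined): 30% incomplete gives `m = 30`. Missing-not-at-random
sensitivity (pattern-mixture adjustment) is out of scope.

## The synthetic trial generator

`generate_trial()` emulates the data structure this analysis assumes — it
is the package's test bed, not a model of any real cohort. Defaults fix
the study conditions: 162:88 allocation, waves at 0/7/12/18 months, a
true 12-month QALY difference of 0.032, a true saving of £909 in
non-intervention care over 12 months (and a zero arm difference on the
12–18-month interval, consistent with the near-constancy of that
difference over the longer horizon), an intervention cost of about £5000
per participant, a one-point true advantage on the depression scale, and
30% of participants with incomplete follow-up, missing at random given
baseline severity.

Key design choices:

* **Counts, not costs, are primitive.** Resource use is drawn per category
  and interval from negative-binomial distributions (configurable to
  moment-matched truncated normal), then priced through the same costing
  code real data would use. Category rates are scaled so that the
  expected 12-month cost difference equals the configured truth exactly
  under the packaged unit costs, with the lower talking-therapy use in the
  intervention arm contributing part of the saving.
* **Utilities are generated on the utility scale and snapped to the
  nearest attainable EQ-5D-3L state**, so the pipeline consumes genuine
  five-digit profiles. Quantisation moves individual utilities by up to
  the local grid spacing; its arm-differential effect on mean QALYs is
  small but not exactly zero, so the generator also keeps the latent
  utilities (`u_lat_*`), and the noise-free exactness property (estimated
  QALY difference equal to the injected truth to 1e-8) is stated and
  tested on that latent path with `utility_source = "latent"`.
* **Severity links the pieces.** Baseline depression drives resource-use
  rates (mean-normalised, so expected costs are unchanged), utility
  trajectories, and — under MAR — the probability of an incomplete
  record, whose logistic intercept is solved numerically so the marginal
  rate matches the configured fraction. The direct utility effect is
  solved so that the total injected QALY difference, including the
  severity-mediated part, hits the target.
* **One seed, hierarchical streams.** Every participant draws from a
  sub-stream derived from the master seed and their id, so enlarging an
  arm never reshuffles existing participants' data, and masking uses a
  separate stream.
* **Missingness is participant-level and monotone** from month 7 or 12
  onward, so the configured fraction is exactly the fraction of
  participants with incomplete 12-month service-use data (the quantity
  the m rule uses). EQ-5D and depression scores are masked jointly with
  the cost blocks at a configurable rate (default 0.8). Medication
  histories and therapy records are treated as fully ascertained.
* **The therapist hourly rate is calibrated** (`calibrate_therapist_rate()`)
  so the expected micro-costed intervention cost matches the configured
  target given the session structure: 29 offered individual sessions with
  mean attendance 22.8, 27 group sessions charged per invitee under the
  actual partition into groups of about seven with the two-therapist
  staffing rule (group attendance averaging 19.3 of 27 affects only the
  attended-basis sensitivity scenario, since invitees are charged
  regardless).

What the generator does **not** emulate: clinical trajectories beyond one
severity score per wave, therapist caseloads, session content, seasonal
or centre effects, and misreporting. Passing tests therefore demonstrate
that the estimator recovers known truths under the assumed data-generating
structure — not that any particular real dataset satisfies it.

Variances are a calibration choice, not a reported quantity: participant-
level spreads were set so that a 250-participant trial yields a cost-
difference CI half-width of roughly £900 and a QALY-difference standard
error of roughly 0.02, the orders of magnitude a trial of this size and
population produces. Where the occasion-level utility noise (SD 0.2),
subject intercept (SD 0.15), severity slopes and count dispersions were
not dictated by any reported moment, they were chosen once as plausible
for a refractory-depression population and left alone.

## Numerical choices and degenerate inputs

* Ties when snapping a utility midway between two states go to the
  better state; ties in the plane's quadrant classification use the
  half-open convention (`> 0` versus `<= 0`) on both axes.
* A zero effect difference leaves the ICER undefined and flagged, never
  an error; dominance language is attached only off the axes.
* Bootstrap resamples that produce a singular fit are redrawn, capped at
  100 per dataset.
* `choose_m()` rounds half-up (12.5% gives 13) to match the printed
  30% → 30 anchor, and never returns less than 2.
* Costs are carried at full precision throughout; rounding (2 dp,
  thousands separators) is a rendering concern. Conservation tests rely
  on this.
* Percentile intervals use the default quantile definition on the pooled
  cloud.
* `cea_analysis(resample = FALSE, B = 1)` is a test hook collapsing the
  bootstrap to the point estimates.

## Problem sizes used in the test suite

Simulation-based tests are sized to the smallest n that leaves the
assertion's Monte-Carlo error well inside its tolerance: masking-rate and
moment checks use 5 000–6 000 participants, imputation-consistency checks
2 000–3 000 rows, the full-pipeline recovery check 2 000 participants with
`m = 30`, the CEAC endpoint check 250 participants with `m = 10` and
`B = 500`, and the coverage study 200 repetitions of a 250-participant
no-missingness trial with `B = 400`. Tolerances are 3 standard errors of
the quantity under test throughout.

## Known limitations

* The conditional models in the imputer are linear-index models;
  interactions or splines must be added as columns by the caller.
* The logistic imputation draw uses the asymptotic posterior
  approximation, adequate away from separation.
* ICER confidence intervals are deliberately absent (ratio statistics
  need Fieller-type or transformed intervals; the CEAC carries the
  decision-relevant uncertainty instead).
* The generator's four-wave schedule (0/7/12/18 months) is fixed; other
  schedules would need new trajectory anchors.
* No value-of-information analysis and no extrapolation beyond the last
  assessment.
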