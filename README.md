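# ceatk — trial-based cost-utility analysis

Economic evaluations run alongside randomised trials ask a blunt question:
is the extra cost of a new intervention justified by the extra health it
produces? `ceatk` is an R package for answering it the way health
economists working to NICE conventions do — for trial statisticians and
health-economics analysts who need the full pipeline from raw
participant-level data to an acceptability curve, with every step testable.

The package grew around the evaluation of an intensive group-and-individual
psychotherapy added to usual care for refractory depression, and it ships a
synthetic-trial generator that emulates that data structure (a 250-person
162:88 two-arm trial, assessments at 0/7/12/18 months, ~30% incomplete
follow-up service-use data) so the whole pipeline runs and is tested
without any confidential data.

## What it computes

For intervention vs control over a horizon (12 months primary, 18 in
sensitivity analysis):

* **Utilities and QALYs** — EQ-5D-3L five-digit profiles scored under a
  configurable tariff (UK TTO value set packaged; full health = 1, worst
  state 33333 = −0.594), QALYs by the area-under-the-curve (trapezoid)
  method, `u·T/12` exact for constant trajectories.
* **Costs** — unit-costed health/social-care contacts, medication costs
  from dated records, a micro-costed intervention (therapist time at an
  hourly employment cost weighted by a 1:0.91 direct:non-direct ratio;
  closed group sessions allocated across all invitees), and productivity
  losses by the human capital approach, kept outside the NHS/PSS total.
* **Missing data** — chained-equations multiple imputation (predictive
  mean matching) at the aggregate level, with `m` set to the percentage of
  incomplete records (30% → m = 30) and Rubin's rules for pooling.
* **Uncertainty** — a non-parametric bootstrap nested in the imputations
  (B resamples per imputed dataset, stratified by arm, both adjustment
  regressions refit per resample; B = 1000 × m = 30 → a 30 000-replicate
  cloud), summarised as

  * ICER = ΔC/ΔE with cost-effectiveness-plane quadrant shares, and
  * the CEAC: P(λ·ΔE − ΔC > 0) over a willingness-to-pay grid.
* **Scenarios** — complete case; adding absenteeism costs; a flat national
  rate per attended group session instead of the micro-costed allocation;
  an 18-month horizon; and cost per depression-scale point.

## Worked example

```r
library(ceatk)

design <- trial_design(seed = 1)        # 162:88, waves 0/7/12/18, 30% MAR
trial  <- simulate_trial(design)        # one row per participant
ana    <- build_analysis_table(trial)   # aggregate costs, QALYs, scores
res    <- cea_analysis(ana, m = 10, B = 500, seed = 1)
res
#> <cea_result> 12 months, m = 10, B = 500 ( 5000 replicates )
#>   delta cost:        3838 GBP  (95% CI 2569 to 4931)
#>   delta effect:    0.0565 QALY (95% CI 0.0206 to 0.0914)
#>   ICER: 67927 GBP per QALY (more effective and more costly)
#>   P(cost-effective): 0.001 at 20000, 0.006 at 30000 GBP/QALY
```

Read: the intervention arm cost £3838 more per participant over 12 months
(bootstrap 95% CI £2569–£4931) and gained 0.0565 QALYs, i.e. about
£68 000 per QALY — far above the £20 000–£30 000 thresholds, so the
probability of cost-effectiveness there is essentially zero. (This is one
synthetic replicate: the generator's true differences are £4091 and
0.032; at n = 250 the QALY estimate carries an SE of about 0.02.)

`tidy(res)` and `glance(res)` return the broom-style tables,
`autoplot(res, "plane")` / `autoplot(res, "ceac")` the two standard
figures, and

```r
run_scenarios(ana, B = 1000, seed = 1)
summarise_completeness(ana)
#>   group            n n_complete pct_complete
#>   control         88         64           73
#>   intervention   162        112           69
#>   overall        250        176           70
summarise_costs(cost_breakdown(trial), covariates = c("age", "female", "hrsd_m0"))
```

give the sensitivity-scenario table and the completeness and disaggregated
cost summaries. A thin command-line wrapper lives at
`inst/scripts/ceatk.R` (`simulate | run | report`).

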