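# ceatrial

Trial-based cost-effectiveness analysis with intersectoral costs and
benefits, for two-arm (cluster) randomized prevention trials.

Health-economic evaluations of school-based behavioural interventions
need more than the health-care ledger: most of the money moved by
adolescent risk behaviour sits in *other* sectors — school absence,
truancy enforcement, household help, police contacts, court proceedings.
`ceatrial` implements the full pipeline for such an evaluation:

* **Costing** — volumes of service use valued with unit prices, indexed
  to a reference year, classified into the health-care sector, four
  intersectoral cost-and-benefit (ICB) sectors (education, labor &
  social security, household & leisure, criminal justice) and a separate
  substance-use sector; per-participant totals from a health-care and a
  societal perspective.
* **Screening** — plausibility limits for open-ended answers (strict
  "more than" rule, e.g. >120 hospital days in a 120-day window),
  complete-case exclusion of cost non-responders, cost-outlier rules,
  and an auditable participant-flow report.
* **Inference** — incremental costs and effects, the ICER
  (C<sub>i</sub>−C<sub>c</sub>)/(E<sub>i</sub>−E<sub>c</sub>),
  nonparametric within-arm bootstrap (customarily 5000 replicates),
  cost-effectiveness plane quadrant proportions, median-of-bootstraps
  ICER with dominance labels, percentile confidence intervals, and
  cost-effectiveness acceptability curves (CEACs) under the
  net-monetary-benefit rule λ·ΔE − ΔC > 0.
* **Scenarios** — base case per perspective × outcome, sensitivity
  analyses (cost outliers excluded; substance costs excluded) and
  dichotomized subgroup analyses (gender, age 15–16 / ≥17, education,
  religion, ethnicity), rendered to CSV tables with a reproducibility
  manifest.
* **Synthetic trials** — a cluster-RCT generator with known ground truth
  (school-level ICC, zero-inflated right-skewed volumes, systematic
  unrealistic-answer contamination, covariate-dependent ~70% dropout) so
  every stage is testable without access to trial data.

See `vignettes/trial-cea-methods.Rmd` for the model details and design
decisions.

## Worked example

```r
library(ceatrial)

# a synthetic trial at the default study conditions:
# 34 schools x 78 adolescents, ICC 0.01/0.06, true incremental effect
# 0.73 glasses/week, 3.4% contamination, ~70% dropout
trial <- generate_trial(trial_scenario(seed = 1))
analysis <- prepare_analysis_set(trial$participants)
analysis$flow
#> Participant flow
#>   start: n = 2652
#>   - unrealistic answers (T0): excluded 103 (3.88%) -> n = 2549
#>   - no cost answers at T0: excluded 65 (2.55%) -> n = 2484
#>   - did not participate at T1: excluded 1695 (68.24%) -> n = 789
#>   - unrealistic answers (T1): excluded 0 (0%) -> n = 789
#>   - no cost answers at T1: excluded 30 (3.8%) -> n = 759

config <- scenario_config(n_reps = 5000, seed = 1, subgroups = list())
base <- run_base_case(analysis, config)
base$healthcare_weekly$bootstrap
#> Bootstrap CEA: 5000 replicates (seed 1307047620)
#>   point: dC = 83.31, dE = 0.277, ICER = 300.93 (ratio)
#>   quadrants: NE 82%, NW 18%, SW 0%, SE 0%
```

Reading: after screening, 759 complete cases remain. From the
health-care perspective the intervention arm cost €83.31 more per
adolescent (the €53 programme cost plus higher service use) and reduced
weekly drinking by 0.28 glasses more than control — an attenuated
realization of the latent 0.73-glass effect, since follow-up outcomes
are floored at zero (see the vignette). 82% of bootstrap replicates land
in the northeast quadrant (more effective, more costly); the median
bootstrap ICER is €195 per extra glass/week reduced, and the CEAC rises
from 0.002 at a willingness to pay of €0 through 0.64 at €500 to 0.75 at
€1000:

```r
icer <- base$healthcare_weekly$icer
round(icer$value, 1)
#> [1] 195.1
cv <- base$healthcare_weekly$ceac
cv$probability[cv$wtp %in% c(0, 250, 500, 1000)]
#> [1] 0.0024 0.4272 0.6440 0.7454
```

The 95% percentile CI for ΔE, `[-0.30, 0.85]`, covers both zero and the
latent effect — a single simulated trial of this size is underpowered
for the effect, which is exactly what the CEAC quantifies.

`run_scenarios()` wraps base case, sensitivity and subgroup analyses in
one call and `render_reports()` writes the CSV tables, plane/CEAC point
files and a run manifest. A thin command-line wrapper lives at
`inst/cli/ceatrial.R`.

The shipped `inst/extdata/unit_costs.yaml` holds **illustrative
placeholder prices** (real analyses must supply their own unit-cost
manual values and price-index factors); `inst/extdata/limits.yaml` holds
the editable plausibility limits, with the 120-hospital-day rule
preloaded.

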