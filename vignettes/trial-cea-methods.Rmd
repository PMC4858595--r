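---
title: "Methods: trial-based cost-effectiveness analysis with intersectoral costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trial-based cost-effectiveness analysis with intersectoral costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceatrial)
```

## The evaluation problem

`ceatrial` implements the economic-evaluation pipeline for a two-arm
cluster-randomized prevention trial in which schools are randomized to a
behavioural intervention or to care as usual, outcomes are measured at
baseline (T0) and after roughly four months (T1), and resource use over
the recall window is self-reported through open-ended questionnaire
items. The motivating use case is a web-based alcohol-prevention
programme for adolescents aged 15–19, with two effect measures:

* **weekly alcohol use** (glasses per week), and
* **binge-drinking occasions** in the preceding 30 days.

Effects enter the analysis as *change scores*: the T1 value subtracted
from the T0 value, so a positive score is a reduction in drinking. Costs
enter from one of two perspectives: a *health-care perspective* (health
services plus the intervention itself) and a *societal perspective* that
adds intersectoral costs and benefits (ICBs) — costs falling on the
education, labor and social security, household and leisure, and
criminal justice sectors — plus the costs of other substance use.
Substance-use costs are held in their own sector so the "without
substance costs" sensitivity scenario is a column toggle rather than a
re-costing. Alcohol purchases are never costed: alcohol consumption is
the effect measure, and valuing it as a cost would double count.

## Costing model

Each of the 20 volume categories (`cost_categories()`) is valued as
`volume × unit price`, with unit prices indexed to the reference year by
the ratio of price-index factors (`index_price()`). Currency arithmetic
rounds half-up at the cent at the category level, so sector and
perspective totals are exact sums of their members — an invariant the
test suite asserts on random volume vectors.

The per-participant intervention cost is built up from a weekly
tailored-feedback software fee and a valuation of participant time
(supervised school hours at an hourly rate plus a lump value for own
time), the time component rounded to the nearest Euro:

```{r}
intervention_cost(intervention_cost_spec(), "feedback")
intervention_cost(intervention_cost_spec(), "time")
intervention_cost(intervention_cost_spec())
```

The intervention cost is attributed to intervention-arm participants
only (a waiting-list control receives the programme after the trial);
`arm_rule` makes this configurable for other designs.

The shipped `unit_costs.yaml` contains *illustrative placeholder
prices*. National costing manuals are licensed documents whose values
are not reproduced here; real analyses must substitute their own prices
and price-index factors.

## Screening rules

Open-ended questionnaires invite unrealistic answers, and a small
subsample tends to produce them systematically. Screening therefore
applies, in a fixed order:

1. **Baseline**: remove participants breaching any plausibility limit,
   then those who answered no cost question at T0.
2. **Follow-up**: remove T1 non-participants, then limit breaches, then
   those who answered no cost question at T1.

Limits are *strict* upper bounds: "more than 120 hospital days in a
120-day window" is excluded, exactly 120 is retained. The same strict
rule governs the cost-outlier sensitivity exclusion (totals above €5000
are dropped, €5000 itself is kept). Exclusion is always whole-case;
field-level nulling would silently mix respondents into the complete-case
means. Screening is idempotent and never mutates its input, and every
stage lands in a `flow_report` whose percentages are reproducible.

Two percentage conventions coexist in published flow figures (one
truncates at two decimals, the other rounds half-up at one), so
`flow_percent()` takes the convention as an explicit argument rather
than hiding a single choice.

## The bootstrap CEA engine

With arm means $C_i, C_c$ (costs) and $E_i, E_c$ (effects), the
incremental cost-effectiveness ratio is

$$\mathrm{ICER} = \frac{C_i - C_c}{E_i - E_c} = \frac{\Delta C}{\Delta E}.$$

Uncertainty is handled by a nonparametric bootstrap
(`bootstrap_cea()`): participants are resampled with replacement
*within each arm* (sizes preserved), arm means are recomputed jointly
for cost and effect, and each replicate contributes one
$(\Delta C, \Delta E)$ pair. Within-arm resampling is the field
standard for two-arm trials; a cluster bootstrap (resampling schools) is
exposed but off by default, because in the motivating design the
school-level intraclass correlations of the effect measures were small
enough that individual-level resampling was judged adequate.

Replicates are classified into cost-effectiveness-plane quadrants with a
fixed boundary convention — zero $\Delta E$ counts as "not more
effective", zero $\Delta C$ as "not more costly", so the origin falls in
SW. The boundaries have probability zero for continuous data; fixing
them keeps quadrant proportions exactly reproducible.

Summaries:

* **Median ICER** — the 50th percentile of the per-replicate ratios,
  with zero-$\Delta E$ replicates dropped and counted. The raw ratio is
  known to be pathological across quadrants (the same negative number
  means opposite things in SE and NW), which is why the result carries
  the point-estimate dominance label and why the CEAC is provided as the
  statistically sound companion.
* **Percentile CIs** — plain percentile intervals (type-7 quantiles);
  no Fieller or BCa correction is applied, matching the plain-percentile
  practice the pipeline reproduces.
* **CEAC** — for each willingness-to-pay $\lambda$ the probability of
  cost-effectiveness is the fraction of replicates with positive net
  monetary benefit, $\lambda \Delta E - \Delta C > 0$. At $\lambda = 0$
  this equals the cost-saving mass (SE + SW). Reports sometimes equate
  the $\lambda = 0$ probability with the SE share alone; with a small SW
  share the two nearly coincide, but the NMB definition is what is
  implemented. The default grid is €0–1000 in €10 steps.

Quadrant percentages in rendered tables are integers allocated by
largest remainder, so each row sums to exactly 100; the CSV point files
keep full precision.

## Descriptive statistics

Baseline comparability is assessed with uncorrected Pearson chi-square
tests for discrete variables and pooled-variance Student t tests
(reported as magnitudes) for continuous ones. Chi-squares on integer
counts are exact anchors; t statistics recomputed from rounded published
summaries are not, so tests validate the t implementation against the
textbook formula instead. Cost skewness is diagnosed with the adjusted
Fisher–Pearson skewness $G_1$ divided by its exact small-sample standard
error; values above 1.96 indicate the right-skew typical of cost data.

The intraclass correlation uses the one-way ANOVA variance-components
estimator: $\rho = s_b^2 / (s_b^2 + s_w^2)$ with
$s_b^2 = \max(0, (\mathrm{MSB} - \mathrm{MSW})/n_0)$ and the
imbalance-adjusted average cluster size $n_0$. The method-of-moments
route is dependency-free, agrees with a mixed model in the balanced
case, and the zero-truncation keeps $\rho \in [0, 1]$.

## The synthetic-trial generator

`generate_trial()` emulates the study conditions so the pipeline is
testable without any real data. Defaults: 17 schools per arm × 78
adolescents (≈2650 at baseline), ICC targets 0.01 (weekly use) and 0.06
(binge occasions), incremental effects 0.73 glasses/week and 0.49
occasions, a secular drift of +1.51 glasses/week (+0.33 occasions)
affecting everyone, 3.4% systematic unrealistic answering (each spoiled
record gets $2 + \mathrm{Poisson}(0.9)$ absurd fields, mean 2.9), ~70%
follow-up attrition with covariate-dependent (hence not-at-random)
selection, and ~2.5%/5.3% missing cost answers at T0/T1. Baseline
imbalance offsets make the intervention arm more female, higher
educated and slightly more religious, mirroring the compositional
differences cluster randomization can produce.

Design choices worth knowing:

* **Volume models.** Count-like categories are zero-inflated negative
  binomial; hour-like categories zero-inflated log-normal. Both
  reproduce the zero-heavy, right-tailed shape of short-horizon service
  use; the per-category levels are free calibration choices recorded in
  `default_volume_models()`.
* **Clustering enters outcomes only.** School random intercepts are
  added to the latent change scores; cost volumes are generated without
  cluster structure, since only the effect measures carry ICC targets.
* **One RNG stream per stage.** Each generation stage derives its seed
  from the scenario seed and a fixed label, so adding or disabling a
  stage never perturbs earlier draws, and the whole table is
  bit-identical under a fixed seed.
* **Ages** are drawn uniform over 15–19 whole years; drinking-age
  threshold effects are deliberately not modelled.
* **Bounded outcomes.** Follow-up values are floored at zero (binge
  occasions also capped at 30). When much of the sample sits at zero,
  flooring attenuates both the realized arm effect and the realized
  ICC relative to their latent targets — as with real bounded outcomes.
  Estimator-recovery checks (ICC convergence, CI coverage of the true
  incremental effect) therefore use high-baseline scenarios where the
  floor is inactive; pipeline-behaviour checks use the zero-heavy
  defaults. Passing tests show the estimators are correct and the
  pipeline handles realistically messy data, not that latent parameters
  survive the floor unattenuated.

## Problem sizes used in the checks

Test and acceptance runs use deliberately modest sizes chosen as
adequate for their purpose: exhaustive bootstrap enumeration at ≤3
participants per arm (oracle equivalence), 200 clusters × 20 for ICC
convergence (±0.03), 200 replicate trials of 12 schools × 15 for 95%
CI coverage, and 5000 bootstrap replicates for the end-to-end synthetic
CEA — the same replicate count customary for reported analyses.

## Known limitations

* Complete-case analysis only: no imputation machinery is provided, in
  line with the motivating trial's choice to leave a >70%-missing
  follow-up unimputed.
* The generator's single volume vector represents the follow-up recall
  window; baseline screening applies the same limits to it, a
  simplification of two-wave cost questionnaires.
* No discounting (4-month horizon) and no QALY valuation; effects are
  trial-native behavioural units, which is also why no external
  willingness-to-pay threshold exists and the CEAC carries the decision
  burden.
* Printed ICER medians and quadrant percentages of any specific trial
  are not reproducible without its participant-level data; the package
  reproduces the arithmetic anchors that are derivable from published
  summaries and validates everything else by construction on synthetic
  data.
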