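Package: ceatrial
Title: Trial-Based Cost-Effectiveness Analysis with Intersectoral Costs
    and Benefits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the economic evaluation of two-arm (cluster)
    randomized trials of behavioural interventions, built around a
    school-based alcohol-prevention use case.  Volumes of service use are
    valued with unit prices, indexed to a reference year, and classified
    into the health-care sector and intersectoral cost-and-benefit (ICB)
    sectors (education, labor and social security, household and leisure,
    criminal justice), with substance-use costs kept as a separate toggle.
    Participant-level data are screened with plausibility limits and
    complete-case rules into an auditable participant-flow report.  The
    inferential core computes incremental costs and effects, nonparametric
    bootstrap distributions of the incremental cost-effectiveness ratio
    (ICER), cost-effectiveness plane quadrant proportions, percentile
    confidence intervals, and cost-effectiveness acceptability curves
    (CEACs) under a net-monetary-benefit rule.  A synthetic cluster-RCT
    generator with known ground truth (school-level intraclass
    correlation, zero-inflated right-skewed cost volumes, deliberate
    unrealistic-answer contamination, covariate-dependent dropout) makes
    the whole pipeline testable without access to trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
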