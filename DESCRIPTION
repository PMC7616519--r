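Package: heatcc
Title: Heat-Health Case-Crossover Comparison of Overlapping Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing heat-health associations estimated from two
    overlapping but non-linkable encounter datasets: percentile-threshold
    heatwave spell detection from daily county temperature series, grouping of
    claims into emergency-department and inpatient encounters, person-time and
    direct-standardization weights, space-time-stratified case-crossover
    estimation via conditional quasi-Poisson regression with stratum
    elimination, and a combined-dataset ratio-of-incidence-rate-ratios (rIRR)
    estimator with interaction terms. Includes a synthetic-data generator with
    known ground-truth effects and Monte-Carlo experiments contrasting the
    rIRR estimator with naive coefficient-difference and
    confidence-interval-overlap rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
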