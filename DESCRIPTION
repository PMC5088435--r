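Package: dynprof
Title: Dynamic Profiling for Staged Risk Stratification of Longitudinal
    Biomarker Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies longitudinal patient cohorts in stages as biomarker
    readings accrue. Patients are partitioned by k-means (or spectral
    embedding) at each reading round, clusters carry outcome-derived weights
    (death counts, mean and standard deviation of the outcome score), and
    each patient accumulates a risk curve of cluster death probabilities
    over stages. A new patient's outcome is predicted by matching their risk
    curve to the closest curve in the database by area difference. Also
    provides orthogonal-polynomial trend extraction from irregular cytokine
    time series, logistic and probit outcome models built on those trends,
    Beta-Binomial updating of cluster death probabilities, and a synthetic
    cohort generator for severe traumatic brain injury-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
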