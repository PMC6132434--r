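Package: isosub
Title: Isotemporal Substitution Modelling of Accelerometer-Measured Time Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how reallocating time between sedentary
    behaviour, light physical activity (LPA) and moderate-to-vigorous
    physical activity (MVPA) relates to cardiometabolic risk markers in
    children and adolescents.  Processes epoch-level accelerometer count
    streams (reintegration, non-wear detection, wear-time validity,
    count-threshold intensity classification) into per-person daily
    summaries; fits the three-step modelling framework (single-factor,
    partition and isotemporal substitution models) with random study
    intercepts estimated by feasible generalised least squares and
    cluster-robust variance aggregated by study; converts coefficients
    into relative effects against stratum means; and simulates synthetic
    multi-study cohorts with planted reallocation effects so that every
    stage can be tested without access-restricted pooled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    sandwich,
    lme4,
    optparse
Config/testthat/edition: 3
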