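Package: chamberqc
Title: Quality Control and Stability Assessment for Controlled-Environment
    Agriculture Sensor Streams
Version: 0.1.0
Authors@R:
    person("chamberqc", "maintainers", email = "maintainers@chamberqc.dev",
           role = c("aut", "cre"))
Description: Tools for assessing the data quality and operational stability of
    controlled-environment agriculture (growth chamber) temperature sensor
    streams. Builds median diurnal surrogate profiles to impute missing data,
    extracts residuals by an alternative (surrogate-subtraction) decomposition
    or the classical additive decomposition, flags outliers by residual
    z-scores at a configurable significance level, fits candidate
    distributions to outlier severities with AIC/BIC model selection, converts
    door and person-presence event logs into a cumulative agricultural
    operations covariate, and regresses log outlier severity on that covariate
    with a Gaussian GLM. A deterministic seeded chamber simulator with planted
    anomalies and ground-truth labels makes every stage testable without
    external data. A subcommand command-line interface drives the full
    pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
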