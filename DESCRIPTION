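Package: workrisk
Title: Probabilistic Occupational Exposure and Health Risk Assessment for
    Airborne Chemicals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for probabilistic health risk assessment of airborne
    chemicals in the workplace. Fits candidate parametric distributions
    (log-logistic, lognormal, gamma, Weibull) to workplace air-concentration
    measurements, estimates central tendency exposure (CTE, the fitted
    median) and reasonable maximum exposure (RME, the fitted 95th
    percentile) by Monte-Carlo simulation, derives worker-adjusted
    toxicity reference values (workplace unit risk from a cancer slope
    factor; workplace reference concentrations from points of departure
    under pluggable agency correction-factor schemas), and characterizes
    risk as excess cancer risk and hazard quotients with acceptability
    screening. Includes a seeded synthetic-data generator for workplace
    measurement campaigns and a built-in dossier for biphenyl.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    fitdistrplus,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
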