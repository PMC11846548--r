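Package: equicast
Title: Equity Measurement and Demand Forecasting for Regional Health
    Workforce Panels
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for assessing the equity of health-workforce allocation
    across regions and forecasting workforce demand. Reads region-by-year
    resource panels (population, land area, registered nurses, doctors,
    health technicians, beds), derives standard allocation indicators
    (density per 1,000 population, per square kilometre, doctor-to-nurse
    and bed-to-nurse ratios), measures inequality with Lorenz curves, Gini
    coefficients (with fairness banding) and the decomposable Theil index,
    and produces five-year forecasts with both a from-scratch GM(1,1) grey
    model (including the posterior-difference accuracy test and
    extrapolation gating) and an ARIMA stage with automatic order
    selection. A synthetic-panel generator with known ground truth makes
    every stage testable without external yearbook data.
License: MIT + file LICENSE
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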