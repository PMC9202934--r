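Package: hmrisk
Title: Probabilistic Dietary Risk Assessment of Heavy Metals in
    Wastewater-Irrigated Vegetables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing non-carcinogenic human health risk from
    heavy metals that accumulate in vegetables grown on wastewater-irrigated
    soil. Computes soil-to-plant metal transfer factors (MTF), estimated
    daily intake (EDI), target hazard quotients (THQ) and hazard indices
    (HI) for population groups, propagates parameter uncertainty with a
    seeded Monte Carlo engine (lognormal, truncated-normal, triangular and
    uniform inputs), checks forecast convergence across independent runs,
    and attributes output variance to inputs with Spearman rank-correlation
    contribution-to-variance sensitivity analysis. Ships field concentration
    tables for industrial-wastewater and tube-well irrigation, and a
    synthetic-data generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
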