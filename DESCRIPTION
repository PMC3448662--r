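Package: ironcma
Title: Cost-Minimization Modelling of Intravenous Iron Infusion Strategies
Version: 1.0.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for cost-minimization analysis of ambulatory
    intravenous iron therapy, comparing high-dose ferric carboxymaltose (FCM,
    1000 mg per infusion) with iron sucrose (IS, 200 mg per infusion) in a
    day-care unit. Provides a calibrated synthetic patient-cohort generator,
    an infusion-count dosing model, a per-patient cost model under hospital
    and societal perspectives, deterministic one-way and two-way sensitivity
    analyses with closed-form break-even drug prices, and a seeded Monte
    Carlo probabilistic sensitivity analysis.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
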