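Package: copdwatch
Title: Simulation and Pre-Post Analysis of a Zone-Based COPD Telemonitoring Program
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate, monitor, and analyse a traffic-light ("zone")
    telemonitoring action plan for chronic obstructive pulmonary disease
    (COPD). Provides a synthetic cohort generator calibrated to a secondary
    care exacerbation-prone COPD population, a deterministic zone state
    machine that turns daily symptom questionnaires, on-demand severity
    questions and step counts into green/yellow/orange/red states with buddy
    alerts, per-patient usage summaries, a Poisson generalized estimating
    equation (GEE) fitter with log-exposure offsets and robust standard
    errors for pre-post incidence rate ratios, and a paired-means power
    calculation with dropout inflation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
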