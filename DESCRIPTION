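Package: nnsbia
Title: Budget Impact Modelling of Oral-Stimulation Training in Preterm Infants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus dual-Markov cohort model for the budget impact
    of patterned oro-somatosensory stimulation versus standard-of-care oral
    stimulation to develop non-nutritive sucking in preterm infants
    (gestational age 25-30 weeks). Tracks NICU occupancy, nasogastric-tube
    discharges, infections in hospital and at home, rehospitalisations and
    deaths on a mixed daily/half-monthly cycle grid over five years, and
    attaches unit costs under an insurance-payer (charges, 5-year) or
    hospital (cost-to-charge converted, 1-year) perspective. Includes a full
    uncertainty toolkit: Monte Carlo probabilistic sensitivity analysis with
    kind-specific sampling distributions, one-way (tornado) sensitivity
    analysis, a time-to-discharge factor sweep, device-cost threshold
    analysis and gestational-age subgroup analysis, plus a calibrated
    synthetic parameter fixture so every stage runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
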