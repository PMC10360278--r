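Package: strokesim
Title: Monte Carlo Simulation of Regional Acute Stroke Pathways and the
    Drive-the-Doctor Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of regional acute ischemic stroke
    services for patients with large vessel occlusion treated by
    endovascular thrombectomy.  Models the drip-and-ship baseline pathway
    (primary stroke center first, transfer to a comprehensive stroke
    center) and drive-the-doctor scenarios in which a mobile
    interventionalist travels to an upgraded thrombectomy-capable stroke
    center, with configurable regional spread of centers, prehospital
    patient routing (nearest IVT facility or RACE-scale based),
    interventionalist notification moments and transport modalities (car,
    ground or helicopter EMS).  Estimates onset-to-groin-puncture time,
    predicted probability of favorable outcome from a cumulative-logit
    ordinal model of the modified Rankin Scale, and waiting-time
    synchronization statistics, with common-random-number scenario
    contrasts and preparation-time sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    fitdistrplus,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
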