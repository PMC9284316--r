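Package: dielCN
Title: Diurnal Carbon/Nitrogen Kinetic Modelling of Photorespiration and
    Nitrate Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic ordinary-differential-equation model of the interacting
    photorespiratory carbon cycle and the GS/GOGAT nitrogen assimilation cycle
    in leaf tissue over a light/dark cycle. Builds time-dependent drivers
    (photosynthesis spline from gas exchange, diurnal enzyme-activity splines),
    computes the photorespiratory flux from net CO2 exchange via the
    oxygenation-to-carboxylation ratio, identifies kinetic parameters by
    ensemble particle-swarm optimization against diurnal metabolite time
    courses, runs a nocturnal glutamine-synthetase inactivation scan, and
    extracts reaction fluxes and flux ratios from fitted ensembles. Includes a
    seedable synthetic-data generator emulating a four-condition study
    (wildtype and an hpr1-1-like mutant at ambient and elevated CO2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
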