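Package: calshock
Title: Calcium Signaling Dynamics of the Yeast Hypotonic-Shock Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coupled biophysical and biochemical ODE model of the cytosolic
    calcium transient triggered by hypotonic shock in Saccharomyces
    cerevisiae. The biophysical half tracks osmotic cell volume and turgor
    pressure of a walled cell under a dilution stimulus; the biochemical
    half tracks cytosolic calcium exchanged through the high-affinity
    calcium influx system, a turgor-gated mechanosensitive channel, and the
    Pmc1, Vcx1 and Pmr1 transporters, with calmodulin- and
    calcineurin-mediated feedback inhibition. Includes strain
    parameterisations for in-silico knockouts, steady-state calibration,
    mixing-time scans, flux decomposition, a particle-swarm optimizer for
    parameter estimation against calcium time courses, and a synthetic
    trace generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    jsonlite
Config/testthat/edition: 3
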