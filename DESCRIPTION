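Package: isletchip
Title: Glucose-Insulin Homeostasis Modelling for a Liver-Islet Microphysiological System
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic modelling of glucose-insulin cross-talk in a two-compartment
    liver-islet microphysiological system (organ-on-chip). Provides a fast/slow ordinary
    differential equation model coupling hepatic glucose uptake, glucose-stimulated insulin
    secretion, progressive hepatic insulin resistance and Topp-type beta-cell volume dynamics;
    an event-driven simulator of the 15-day culture protocol with media exchanges, glucose
    tolerance tests and medium sampling; experiment-wise calibration by simulated annealing
    with a chi-square acceptance gate and uncertainty envelopes; in-vitro-to-in-vivo
    extrapolation of operating conditions and rate constants to human scale; and a
    synthetic-data generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
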