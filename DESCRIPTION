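Package: capflow
Title: Flow-Rate Immunoagglutination Assays on Paper Microfluidic Chips
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for capillary flow-rate immunoassays on
    wax-printed paper microfluidic chips. Tracks the wetting front along each
    channel of a video frame stack, models the flow with the Lucas-Washburn
    law to estimate diffusion coefficients and select an optimal detection
    frame, simulates the mass-action kinetics of particle immunoagglutination
    (including the hook effect and particle-concentration curve shifts), and
    provides the assay statistics: Welch t-tests against the negative
    control, limit of detection, four-parameter logistic calibration curves,
    linear-range search, dilution arithmetic and tier classification. A
    synthetic-data module generates ground-truth flow profiles, rendered
    channel videos and replicate assay datasets so the whole pipeline can be
    exercised and tested offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
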