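Package: laminarephys
Title: Laminar Evoked Field Potential and Current Source Density Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stimulus-evoked laminar local field
    potentials recorded along the hippocampal CA1-dentate gyrus axis with
    linear multi-electrode arrays. Implements five-point template measurement
    of fEPSP amplitude and peak/trough latency, granule-layer population-spike
    detection and probability, input/output curves with half-maximal current,
    paired-pulse and train short-term plasticity indices (percent change from
    the first pulse), long-latency re-entrance detection, and one-dimensional
    current source density estimation by the second spatial derivative with
    linear interpolation and self-normalized rendering. Includes a forward
    Poisson simulator of laminar recordings with programmable sink/source
    components and excitability profiles so every analysis stage can be
    verified against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
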