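Package: phototherm
Title: Photothermal Conversion Efficiency from Laser Heating and Cooling Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Evaluation toolkit for plasmonic photothermal agents. Fits the
    lumped-capacitance heating law to laser heating/cooling thermal traces,
    linearizes the cooling phase to obtain the thermal time constant, and
    computes the photothermal conversion efficiency from the steady-state
    energy balance with an optional solvent/container (water control)
    calibration. Includes readers for extinction spectra with LSPR band
    location, infrared thermogram stack handling with region-of-interest
    extraction, an explicit finite-difference heat-diffusion simulator for
    layered tissue-mimicking skin phantoms with a nanoparticle-doped
    inclusion, MTT viability normalization, and seeded synthetic-data
    generators for every input so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
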