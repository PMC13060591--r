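Package: tntsim
Title: Tissue Nanotransfection Field Simulation and Nerve Outcome
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-static simulation of the electric field produced by a
    nanochannel tissue-nanotransfection (TNT) chip at the sciatic-nerve
    interface, with downstream nanoporation and stochastic transfection
    maps, plus the outcome computations used to evaluate nerve repair:
    motor unit number estimation (MUNE) from incremental stimulation,
    compound muscle action potential (CMAP) amplitudes, twitch and tetanic
    torque, grip strength, functional recovery normalization, and
    fluorescence quantification of myelinated axons and capillary density.
    Includes seeded synthetic-data generators (motor-unit pools, EMG and
    torque traces, multichannel nerve micrographs) with embedded ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
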