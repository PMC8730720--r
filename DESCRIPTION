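Package: eccfail
Title: Depolarization-Induced Failure of Excitation-Contraction Coupling
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of depolarization-induced failure of
    excitation-contraction coupling (ECC) in skeletal muscle fibers. Provides a
    seeded synthetic cohort generator that emulates high-potassium infusion
    recordings (action-potential sweeps at 10 kHz plus ROI fluorescence frames
    at 30 frames/s), action-potential feature extraction (peak, half-width,
    integral above a voltage cutoff), dF/F extraction and normalization,
    constrained Boltzmann fitting of the three voltage relationships, threshold
    classification of ECC success and failure along the fiber, conduction
    transition metrics, and cohort-level statistics, orchestrated as a
    reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
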