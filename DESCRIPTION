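Package: pensense
Title: Simulation and Analysis of Small-Molecule Sensing PEN-DNA Switch Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and analysis of isothermal DNA amplification
    switches (polymerase/exonuclease/nickase, "PEN", reaction networks) coupled
    to small-molecule inputs through allosteric transcription factors. Provides
    a kinetic simulator for bistable amplification switches with protein-sensing
    source templates, the time-to-switch (Cq) statistic used on fluorescence
    time traces, Hill dose-response assembly and fitting, two-input classifier
    concentration grids with a weighted log-sum readout, and a two-substrate
    enzyme layer for in-situ metabolic sensing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
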