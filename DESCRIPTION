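Package: neuralclosure
Title: Interpretable Neural Closure Models for 1-D Partial (Delay) Differential Equations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Augments low-fidelity one-dimensional PDE models with trainable
    closure terms: instantaneous (Markovian) closures built as sparse linear
    combinations over a library of candidate terms, and memory (non-Markovian)
    closures built as distributed-delay integrals of small neural networks.
    Both are trained by solving continuous adjoint PDEs backward in time, so
    gradient cost is independent of the number of weights. Ships two wave
    testbeds (KdV-Burgers two-soliton term discovery, Burgers truncation-error
    discovery and generalization against a Smagorinsky baseline) and a 1-D
    plankton-carbonate (NPZD-OA) ocean column in which the framework
    discriminates zooplankton mortality laws and augments an aggregated NPZ
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
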