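Package: evochain
Title: Genetic Parameterization of Passive Multi-Compartment Neuron Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a linear chain of passive leaky integrate-and-fire
    compartments (a spatial discretization of the cable equation) as a virtual
    analog substrate with DAC-controlled conductances, per-sample voltage
    noise, and 10-bit ADC quantization.  Implements the measurement protocol
    for EPSP attenuation along the chain (spike-triggered averaging, peak
    amplitude extraction, exponential length-constant fits), a grid search
    over the two conductance DACs, and a customized genetic algorithm with
    elitism, tournament selection, one-point crossover, and power-of-two
    integer mutation for single-, multi-objective, and nine-dimensional
    parameter searches.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
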