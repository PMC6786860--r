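Package: eqspike
Title: Equation-Oriented Simulation of Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clock-driven simulator for spiking neural networks in which
    models are written as plain-text differential equations annotated with
    physical units. Equations are checked for dimensional consistency,
    compiled to vectorized kernels, and advanced through a fixed
    per-timestep schedule of synaptic coupling, numerical integration,
    thresholding, spike propagation through delay queues, and reset.
    Linear constant-coefficient systems are integrated exactly via the
    matrix exponential; nonlinear systems use explicit or exponential-Euler
    schemes and stochastic systems use Euler-Maruyama. Synapses support
    expression-based connectivity, per-synapse dynamics, transmission
    delays, and continuous graded (summed-variable) interactions.
    Complete network state can be stored and restored to express
    experiment protocols such as parallel bisection searches. Ships with
    runnable fixtures: a homeostatically regulated pyloric circuit, a
    closed-loop ocular pursuit model, voltage-threshold finding by
    bisection, a delay-line pitch detector, and the CUBA random-network
    benchmark.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
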