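Package: arborsim
Title: Branch-Parallel Simulation of Multi-Compartment Hodgkin-Huxley Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of morphologically detailed neuron models
    discretized from SWC reconstructions into tree-structured compartmental
    models with Hodgkin-Huxley style membrane mechanisms.  The cable system of
    each neuron is solved per timestep by a tree-specialized Gaussian
    elimination (Hines solver) that can be split across connected subtrees,
    exchanging exactly three boundary quantities per connection per step.
    Includes a workload-threshold clustering algorithm that decomposes a
    compartment tree into a tree of subtrees, a vector-friendly
    structure-of-arrays memory layout for subtree state, a deterministic
    producer-consumer dataflow runtime executing subtrees as dependency-gated
    tasks, longest-processing-time load balancing across simulated localities
    with terminal-group delegation, and generators for synthetic morphologies
    and networks so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
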