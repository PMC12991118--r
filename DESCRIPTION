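Package: photoplast
Title: Causal-Connectivity and Plasticity Analysis for Optical Brain-Computer
    Interface Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rapid learning in single-neuron optical
    brain-computer interface (BCI) experiments with interleaved two-photon
    photostimulation mapping. Implements the closed-loop BCI transform and
    trial state machine, task-epoch tuning vectors and learning slopes,
    photostimulation repeat-response statistics and masked causal-connectivity
    matrices, cross-validated lasso regression of connectivity on task tuning,
    rate recurrent-network models that discriminate local recurrent from
    upstream plasticity, a hand-wired preparatory circuit model, and a
    synthetic-data generator with known ground truth so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
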