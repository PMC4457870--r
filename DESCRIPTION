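Package: sparseperceptron
Title: One-Class Perceptron Learning with Imbalanced Synaptic Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online learning and offline optimisation for the sign-constrained
    one-class perceptron, a model of recognition memory in a single neuron with
    excitatory (non-negative) synapses. Implements balanced and imbalanced
    potentiation/depression rules whose imbalance acts as an L1 penalty on the
    synaptic weight vector and drives synapses to zero, the offline minimum-L1
    (maximal imbalance) and minimum-L2 (maximal information) reference solutions,
    the Krauth-Mezard min-over algorithm under a non-negativity constraint,
    post-hoc pruning controls, generators for random, correlated and corrupted
    binary input patterns, information and memory-efficiency metrics (bits per
    synapse and per functional synapse), compressed-exponential fits to synaptic
    weight distributions, and the perceptron convergence bound for imbalanced
    plasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    quadprog,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
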