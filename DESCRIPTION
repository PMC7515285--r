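Package: synfacil
Title: Information-Rate Bounds for Synapses with Short-Term Facilitation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a chemical synapse with short-term facilitation as a
    two-state binary asymmetric channel in which the previous presynaptic
    spike selects between baseline and facilitated release probabilities.
    Provides closed-form lower and upper bounds on the mutual information
    rate between the spike train and the release train, energy-normalized
    (bits-per-release) variants, and a classifier of whether facilitation
    increases or decreases either rate. Includes simulators for the
    two-state channel and for a general history-dependent facilitation
    model with exponential relaxation, Bernoulli and inhomogeneous
    sinusoidal-rate spike-train generators, and a context-tree-weighting
    entropy-rate estimator with Krichevsky-Trofimov sub-estimators used
    to estimate the information rates the bounds bracket.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
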