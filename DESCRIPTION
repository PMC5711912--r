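Package: markovbrain
Title: Evolvable Markov Brains with Lifetime-Learning Feedback Gates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An agent-based simulation system for studying the evolution of
    lifetime learning. Markov Brains -- genetically encoded networks of
    deterministic and probabilistic logic gates -- are extended with feedback
    gates, probabilistic gates that adjust their own probability tables from
    internally generated positive and negative feedback via a buffered
    multiplicative update. The package provides the byte-string genome
    representation and its mutation operators, gate decoding and evaluation, a
    procedurally generated arrow-labelled maze navigation task with randomized
    option-to-action mappings, a generational genetic algorithm with
    tournament selection and line-of-descent reconstruction, and analyses of
    lifetime learning (mutual-information change of feedback tables,
    frozen-feedback controls, gate census, action-usage profiles).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
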