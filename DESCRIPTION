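Package: comra
Title: Context-Based Simulation of Individual and Collaborative Free Recall
Version: 0.1.0
Authors@R:
    person("comra", "developers", email = "comra@example.org", role = c("aut", "cre"))
Description: A retrieved-context model of memory search for free recall,
    covering both individuals recalling alone (nominal groups) and
    turn-taking collaborative groups in which each novel recall is
    broadcast and probabilistically attended to by listeners. Provides
    context drift and Hebbian item-context learning, a context-cued
    retrieval rule with an output-position stopping hazard, synthetic
    semantic spaces with controllable clustering, the standard free-recall
    behavioral statistics (serial position curve, probability of first
    recall, semantic similarity by output lag, proportion recalled,
    collaborative inhibition by group size), context-convergence analyses,
    and parameter fitting by sequential model-based optimization of a
    normalized root-mean-square error objective.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
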