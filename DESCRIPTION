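Package: fluxpdf
Title: Flux Distributions in Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the marginal probability density of every reaction flux
    over the steady-state solution space (flux polytope) of a constraint-based
    metabolic model. Two complementary algorithms are provided: weighted Belief
    Propagation (wBP), a message-passing scheme on the bipartite
    reaction-metabolite graph that represents each cavity marginal by a
    weighted population of flux values and evaluates mass-balance integrals by
    rejection-free importance sampling, running in time linear in the number of
    reactions; and Kernel Hit-and-Run (KHR), a provably uniform Markov-chain
    sampler that first reduces the polytope to the null space of the internal
    stoichiometric matrix and then runs Hit-and-Run in the reduced coordinates.
    Utilities generate random sparse test networks, read and write simple
    JSON/TSV network files, and compare marginal estimates across methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
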