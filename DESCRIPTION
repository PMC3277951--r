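Package: mudrug
Title: Multi-Target Drug Screening by Structured Singular Value Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens combinatorial multi-parameter therapies on biochemical
    reaction-network models for robustness to parametric uncertainty.  Given a
    mass-action ODE network with a healthy and a diseased input condition, the
    package builds stochastic-noise-derived performance envelopes (Gillespie
    simulation), enumerates parameter-subset therapies and fits them to the
    healthy response by bounded least squares, screens them for nominal
    performance against the envelope, and certifies robust performance under
    bounded real parameter fluctuations via mu-analysis (linear fractional
    transformation to M-Delta form, D,G-scaling upper bounds and structured
    lower bounds on the structured singular value).  Local sensitivity
    analysis is included for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
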