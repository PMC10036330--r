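Package: triadsync
Title: Synchronization Stability of Hypergraphs with Triadic Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how three-body (triadic) interactions shape the
    stability of full synchronization in higher-order networks. Implements the
    multiorder Laplacian of phase-oscillator systems with pairwise and triadic
    coupling, its second Lyapunov exponent and degree-based spectral bounds;
    generators for random hypergraphs, flag (clique) complexes and related
    ensembles, together with simplex-shuffling and degree-preserving membership
    swap rewiring; degree-heterogeneity theory (quadratic degree law,
    heterogeneity ratio and indexes, Gumbel extreme-value estimates of extreme
    degrees, cross-order degree correlation); and direct numerical integration
    of the triadic Kuramoto model to validate spectral predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    Rcpp,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
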