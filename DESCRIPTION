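Package: moranincub
Title: Incubation-Period Distributions from Moran Dynamics on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Moran Birth-death and Death-birth dynamics of a
    pathogenic invader taking over a network of healthy resident cells, and
    studies the resulting distribution of takeover (incubation) times.
    Provides exact geometric-sum samplers for solvable networks (complete
    graph, one-dimensional ring), asymptotic limit laws (Gumbel and normal),
    the Riemann-zeta skewness of high-dimensional lattices, dispersion-factor
    (geometric standard deviation) statistics, method-of-moments Gumbel and
    shifted-lognormal fits, and experiment runners for truncated takeover
    thresholds, heterogeneous hosts and doses, and non-static populations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
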