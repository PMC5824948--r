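Package: attractorscape
Title: Attractor Landscape Analysis of Boolean Biomolecular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of Boolean models of
    biomolecular regulatory networks. Networks are defined by signed,
    weighted interactions with basal expression values, or by per-node
    Boolean update rules. The package enumerates or samples the binary
    state space, finds point and cyclic attractors with their basins of
    attraction, computes steady-state probability distributions under a
    noisy update rule (exact master-equation iteration or trajectory
    sampling), maps attractors to cell-fate labels through user-defined
    logic, screens single and combinatorial network perturbations for
    fate reprogramming, and projects state spaces onto two-dimensional
    potential-energy landscapes via Sammon or naive mapping. Bundled
    fixtures include the 11-node budding-yeast cell-cycle network and
    synthetic cancer-signalling benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
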