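Package: topoproof
Title: Post-Passage Proofreading Simulation of Topoisomerase II Linking-Number Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic three-gate model of type-II DNA topoisomerase acting on
    covalently closed plasmids, tracking integer linking-number (Lk) topoisomer
    distributions. Implements equilibrium supercoiling energetics (Boltzmann
    topoisomer distributions, quadratic free energy, thermal shift of the
    relaxed center), a kinetic proofreading gate cycle (detailed-balance
    T-segment capture at the N-gate, unidirectional passage, release-versus-
    backtrack competition at the C-gate), closed-form and numerically solved
    stationary distributions, Monte Carlo plasmid ensembles with mid-run
    perturbation protocols (AMPPNP/ICRF-193 N-gate block, disulfide-locked or
    deleted C-gate, temperature shifts), the Lk-distribution statistics used in
    topology-simplification assays (variance, R_Lk, Lk centers, topoisomer
    ratios, parity split), and a synthetic agarose-gel densitometry layer that
    renders lane profiles and quantifies them back into band tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
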