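Package: chirosim
Title: Spatial Monte-Carlo Simulation of Homochirality Emergence in an RNA World
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based stochastic simulation of the concomitant origin of
    biological homochirality and RNA on a toroidal lattice. Chiral nucleotide
    precursors, nucleotides and RNA chains inhabit grid rooms and undergo
    racemization, nucleotide formation and decay, surface-mediated (de novo)
    ligation with a primer effect, template-directed replication with chiral
    selection and cross-inhibition, degradation, strand separation and
    diffusion. Sequence-defined ribozymes (a nucleotide synthetase and an RNA
    replicase) may emerge and feed back on the chirality dynamics. The package
    provides the simulation engine, named scenario presets reproducing the
    published experimental regimes at reduced scale, parameter-sweep drivers,
    and trajectory/snapshot observables including the enantiomeric excess
    statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
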