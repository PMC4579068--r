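Package: aridiv
Title: Diversification Rates, Rate-Shift Detection and Ancestral Ranges for
    Dated Phylogenies
Version: 0.1.0
Authors@R: person("aridiv", "maintainers", email = "aridiv@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing dated, ultrametric phylogenies (chronograms)
    of incompletely sampled clades: lineage-through-time curves and null
    envelopes from Yule/birth-death simulations with random taxon pruning,
    whole-clade and per-node speciation-rate estimators (Baldwin-Sanderson and
    Magallon-Sanderson), a piecewise-constant reconstructed birth-death
    likelihood with a present-day sampling probability and grid-search
    detection of diversification-rate shifts with likelihood-ratio tests, and
    dispersal-vicariance (DIVA/S-DIVA) ancestral-range reconstruction over a
    representative tree and a posterior tree sample. Includes a synthetic-data
    generator with recorded truth so every stage can be validated without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
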