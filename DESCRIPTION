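Package: pemnet
Title: Phenotypic Essential Metabolites in Stoichiometric Metabolic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies internal metabolites of a stoichiometric metabolic
    network as phenotypic essential metabolites (PEMs) with respect to a
    targeted reaction (typically biomass). Three complementary semantics are
    implemented: sustainability (graph-based network expansion / scope
    closure), producibility (steady-state mass balance, flux balance
    analysis) and optimal efficiency (single-reaction knockouts against the
    maximal target flux, flux variability analysis). Networks are read from
    and written to SBML (Level 2 and Level 3 with the fbc extension), and
    results are combined into a seven-region overlap classification with
    connectivity-versus-role summaries. Includes programmatic toy-network
    fixtures, report writers and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
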