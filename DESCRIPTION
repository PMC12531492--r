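Package: adaptuc
Title: Growth-Coupled Knockout Design for Adaptation to Unadapted Carbon Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bilevel mixed-integer strain design for constructing adaptive
    laboratory evolution (ALE) starting strains that couple microbial growth to
    assimilation of an unadapted carbon source (e.g. methanol) alongside a
    native cosubstrate.  Implements the AdaptUC-A (co-dependence on both
    substrates) and AdaptUC-B (growth preserved on the unadapted source alone)
    design variants as single-level MILPs via LP duality, maximising the
    substrate assimilation driving force (SADF) with a Charnes-Cooper
    linearisation of the fractional objective, plus integer-cut enumeration of
    alternative knockout sets.  Includes flux balance analysis primitives,
    SBML-L3/FBC and BiGG-style JSON model I/O, heterologous pathway insertion
    (RuMP methanol assimilation), candidate-knockout prefiltering, evaluation
    metrics (SADF, parsimonious UC/Co uptake ratio, minimal-uptake growth
    curves, biomass-precursor producibility and coupling class), and a
    parametric toy-network generator with closed-form answer keys and an
    exhaustive brute-force design oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    reticulate,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
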