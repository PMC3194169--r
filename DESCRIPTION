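Package: mereocoll
Title: Mereological Design Patterns for Collectives, Compounds and Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Executable mereology for ontology engineering. Finite instance
    models of part-whole reality with the relations has_proper_part, has_grain
    (collective to uniform grain) and has_component (compound to partition
    segment); a four-way classifier of complex entities (flexible/strict
    collectives and compounds); a small description-logic class-expression
    language with finite-model semantics, a Manchester-style parser, an OWL
    DL simplicity (non-simple role) checker and a bounded-model subsumption
    oracle with countermodel search; and a compiler from mereological design
    patterns (collective, n-collective, molecule composition, flexible
    compound, mixture-of-fractions) to OWL 2 class axioms, including a
    regenerated propanol mixture ontology whose three mixture variants are
    all classified as propanol collectives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils-graph.R'
    'AllClasses.R'
    'AllGenerics.R'
    'registry.R'
    'model.R'
    'relations.R'
    'classify.R'
    'dl-expr.R'
    'dl-parse.R'
    'dl-semantics.R'
    'dl-safety.R'
    'subsumption.R'
    'patterns.R'
    'propanol.R'
    'owl-emit.R'
    'owl-parse.R'
    'reasoner.R'
    'theorems.R'
    'fixtures.R'
    'cli.R'
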