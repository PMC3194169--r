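test_that("the collective pattern has the canonical shape", {
  axs <- collPattern("H-Atom")
  expect_length(axs, 1L)
  a <- axs[[1L]]
  expect_identical(a@type, "equiv")
  expect_identical(a@lhs@name, "H-Atom_COLL")
  expect_identical(renderClassExpr(a@rhs),
                   "has_grain some H-Atom and has_grain only H-Atom")
  # applying a pattern twice adds nothing
  ont <- ontology("t", typeRegistry("H-Atom"))
  ont <- addAxioms(ont, collPattern("H-Atom"))
  n1 <- length(axioms(ont))
  ont <- addAxioms(ont, collPattern("H-Atom"))
  expect_identical(length(axioms(ont)), n1)
})

test_that("the n-collective pattern fixes the cardinality", {
  axs <- nCollPattern("Kidney", 2)
  pair <- axs[[length(axs)]]
  expect_identical(pair@lhs@name, "Kidney_PAIR")
  expect_identical(
    renderClassExpr(pair@rhs),
    "Kidney_COLL and has_grain exactly 2 Kidney and has_grain only Kidney")
  one <- nCollPattern("Cow", 1)[[2L]]
  expect_identical(
    renderClassExpr(one@rhs),
    "Cow_COLL and has_grain exactly 1 Cow and has_grain only Cow")
  expect_error(nCollPattern("Cow", 0), "n >= 1")
})

test_that("molecule pattern variants spell the same composition", {
  water <- c(`O-Atom` = 1L, `H-Atom` = 2L)
  flat <- moleculePattern("Water_Molecule", water, "flat")[[1L]]
  expect_identical(
    renderClassExpr(flat@rhs),
    paste("has_component exactly 1 O-Atom and",
          "has_component exactly 2 H-Atom and",
          "has_component only (O-Atom or H-Atom)"))
  nested <- moleculePattern("Water_Molecule", water, "nested")
  main <- nested[[length(nested)]]
  expect_match(renderClassExpr(main@rhs),
               "has_component exactly 1 \\(H-Atom_COLL and has_grain exactly 2 H-Atom\\)")
  pp <- moleculePattern("Water_Molecule", water, "proper_part")[[1L]]
  expect_length(isDLSafe(pp@rhs), 2L)
  expect_match(renderClassExpr(pp@rhs), "not Atom")
  # peroxide gets a different axiom set than water
  flatP <- moleculePattern("Hydrogen_Peroxide_Molecule",
                           c(`O-Atom` = 2L, `H-Atom` = 2L), "flat")[[1L]]
  expect_false(exprIdentical(flat@rhs, flatP@rhs))
})

test_that("flat and nested water agree on their canonical fixtures and both reject peroxide", {
  water <- c(`O-Atom` = 1L, `H-Atom` = 2L)
  flat <- moleculePattern("Water_Molecule", water, "flat")[[1L]]@rhs
  nested <- moleculePattern("Water_Molecule", water, "nested")
  nestedTb <- tbox(nested)
  nestedE <- nested[[length(nested)]]@rhs

  w <- makeMolecule("H2O")
  wn <- makeWaterNested()
  p <- makeMolecule("H2O2")
  # each spelling accepts its canonical model shape (direct-component
  # reading)...
  expect_identical(classExtension(flat, w$model, w$registry,
                                  mode = "primitive"), "mol")
  expect_identical(classExtension(nestedE, wn$model, wn$registry, nestedTb,
                                  mode = "primitive"), "water1")
  # ...and both exclude hydrogen peroxide
  expect_length(classExtension(flat, p$model, p$registry,
                               mode = "primitive"), 0L)
  expect_length(classExtension(nestedE, p$model, p$registry, nestedTb,
                               mode = "primitive"), 0L)
})

test_that("flexible compound pattern warns on non-collective components", {
  axs <- flexibleCompoundPattern("Hand", "Finger_COLL")
  expect_identical(renderClassExpr(axs[[1L]]@rhs),
                   "has_component some Finger_COLL")
  a2 <- flexibleCompoundPattern("Alcohol_Molecule", "C_COLL")
  expect_identical(renderClassExpr(a2[[1L]]@rhs),
                   "has_component some C_COLL")
  expect_warning(flexibleCompoundPattern("Hand", "Finger"), "collective")
})

test_that("mixture variants produce the documented shapes", {
  spec <- propanolFractionSpec()
  gd <- mixturePattern("Propanol_Mixture", spec, "grain_disjunction")[[1L]]
  expect_identical(
    renderClassExpr(gd@rhs),
    "has_grain some (N-Propanol_Molecule or I-Propanol_Molecule)")
  st <- mixturePattern("Propanol_Mixture", spec, "supertype")[[1L]]
  expect_identical(renderClassExpr(st@rhs),
                   "has_grain some Propanol_Molecule")
  fc <- mixturePattern("Propanol_Mixture", spec, "fraction_compound")
  main <- fc[[length(fc)]]
  expect_match(renderClassExpr(main@rhs),
               "has_component only \\(Propanol_COLL or not Molecule\\)")
  rf <- mixturePattern("Propanol_Mixture", spec, "reasoner_friendly")
  # no primitive subrole symbol occurs anywhere in the rewrite
  for (a in rf) {
    roles <- unique(c(mereocoll:::.exprRoles(a@lhs),
                      mereocoll:::.exprRoles(a@rhs)))
    expect_true(all(roles %in% c("has_proper_part", "proper_part_of")))
  }
  expect_error(fractionSpec(list(c(grain = "A", coll = "A_COLL")),
                            "T", "G"),
               "at least 2 fractions")
})

test_that("a full pattern build covers every pattern tag", {
  lib <- buildPatternLibrary()
  tags <- unique(sub("\\(.*$", "",
                     vapply(axioms(lib), function(a) a@provenance,
                            character(1))))
  expect_true(all(c(
    "pattern:hierarchy", "pattern:disjointness", "pattern:coll",
    "pattern:n-coll", "pattern:molecule-flat", "pattern:molecule-nested",
    "pattern:molecule-proper-part", "pattern:flexible-compound",
    "pattern:mixture-grain-disjunction", "pattern:mixture-supertype",
    "pattern:mixture-fraction-compound",
    "pattern:mixture-reasoner-friendly", "pattern:collective-proper-part")
    %in% tags))
})

test_that("the propanol ontology regenerates with the documented inventory", {
  ont <- buildPropanolOntology()
  isomers <- grep("^(N|I)-Propanol_Molecule$", ontologyClasses(ont),
                  value = TRUE)
  expect_length(isomers, 2L)
  mixtures <- grep("^Propanol_Mixture_", ontologyClasses(ont), value = TRUE)
  expect_length(mixtures, 3L)
  expect_true("Propanol_COLL" %in% ontologyClasses(ont))
  # the proper-part regime defines the collective without subrole symbols
  tb <- tboxFor(ont, "proper_part")
  for (a in tb@axioms) {
    roles <- unique(c(mereocoll:::.exprRoles(a@lhs),
                      mereocoll:::.exprRoles(a@rhs)))
    expect_true(all(roles %in% c("has_proper_part", "proper_part_of")))
  }
})
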