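test_that("functional syntax round-trips the axiom multiset", {
  ont <- buildPropanolOntology()
  doc <- emitOwl(ont, "functional")
  back <- readOwlFunctional(doc)
  key <- function(o) sort(vapply(axioms(o), function(a)
    paste(a@type, a@provenance, a@regime,
          renderClassExpr(a@lhs), renderClassExpr(a@rhs)), character(1)))
  expect_identical(key(back), key(ont))
  # role declarations survive too
  expect_true(back@tbox@roles$transitive[
    back@tbox@roles$name == "has_proper_part"])
  expect_identical(
    back@tbox@roles$subroleOf[back@tbox@roles$name == "has_grain"],
    "has_proper_part")
})

test_that("emission is deterministic, and re-emission is byte-identical", {
  a <- emitOwl(buildPropanolOntology(), "functional")
  b <- emitOwl(buildPropanolOntology(), "functional")
  expect_identical(a, b)
  expect_identical(emitOwl(readOwlFunctional(a), "functional"), a)
})

test_that("an empty ontology emits a header-only document", {
  ont <- ontology("empty", typeRegistry())
  doc <- emitOwl(ont, "functional")
  expect_match(doc, "Ontology\\(<http://example.org/mereocoll/empty>")
  expect_false(grepl("SubClassOf|EquivalentClasses", doc))
})

test_that("DL-unsafe ontologies are refused without an override", {
  reg <- typeRegistry(c("Atom", "Water_Molecule"),
                      isA = list(c("O-Atom", "Atom"), c("H-Atom", "Atom")))
  ont <- ontology("unsafe", reg,
                  moleculePattern("Water_Molecule",
                                  c(`O-Atom` = 1L, `H-Atom` = 2L),
                                  "proper_part"))
  expect_error(emitOwl(ont), "outside OWL DL")
  expect_match(emitOwl(ont, override = TRUE), "ObjectExactCardinality")
})

test_that("Manchester emission produces frames with annotations", {
  doc <- emitOwl(buildPropanolOntology(), "manchester")
  expect_match(doc, "ObjectProperty: has_proper_part")
  expect_match(doc, "Characteristics: Transitive")
  expect_match(doc, "Class: Propanol_COLL")
  expect_match(doc, "EquivalentTo: has_proper_part some Propanol_Molecule")
  expect_match(doc, "DisjointClasses: N-Propanol_Molecule, I-Propanol_Molecule")
})

test_that("emitted files load back from disk", {
  path <- withr::local_tempfile(fileext = ".ofn")
  emitOwl(buildPropanolOntology(), "functional", file = path)
  back <- readOwlFunctional(path)
  expect_s4_class(back, "Ontology")
  expect_identical(back@name, "propanol")
})
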