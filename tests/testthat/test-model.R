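test_that("buildModel validates entities and rejects parthood cycles", {
  m <- buildModel(
    list(water1 = "Water_Molecule", o1 = "O-Atom", h1 = "H-Atom",
         h2 = "H-Atom"),
    list(c("water1", "o1"), c("water1", "h1"), c("water1", "h2")))
  expect_s4_class(m, "FiniteModel")
  expect_length(entities(m), 4L)

  expect_s4_class(buildModel(), "FiniteModel")
  expect_length(entities(buildModel()), 0L)

  expect_error(buildModel(list(a = "T", b = "T"),
                          list(c("a", "b"), c("b", "a"))),
               "cycle")
  expect_error(buildModel(list(a = "T"), list(c("a", "ghost"))),
               "unknown entity")
  expect_error(buildModel(list(a = character())), "non-empty")
})

test_that("properParts is the transitive closure and never reflexive", {
  m <- chainModel()
  expect_setequal(properParts(m, "a"), c("b", "c"))
  expect_setequal(properParts(m, "b"), "c")
  expect_length(properParts(m, "c"), 0L)

  pr <- makeMolecule("N_propanol")
  pp <- properParts(pr$model, pr$molecule)
  expect_length(pp, 12L)  # sum formula C3H8O
  expect_false(pr$molecule %in% pp)

  w <- makeMolecule("H2O")
  expect_length(properParts(w$model, "h1"), 0L)
  expect_error(properParts(w$model, "nope"), "unknown entity")
})

test_that("grainsOf defaults to direct parts and honours designation", {
  wp <- makeWaterPortion(5L)
  g <- grainsOf(wp$model, wp$portion)
  expect_length(g, 5L)
  expect_true(all(vapply(wp$model@instanceOf[g], identical, logical(1),
                         "Water_Molecule")))

  w <- makeMolecule("H2O")
  expect_length(grainsOf(w$model, "h1"), 0L)

  m <- buildModel(
    list(x = "T", p1 = "T", p2 = "T", p3 = "T", p4 = "T", p5 = "T"),
    lapply(paste0("p", 1:5), function(p) c("x", p)),
    grainDesignation = list(x = c("p1", "p2", "p3")))
  expect_setequal(grainsOf(m, "x"), c("p1", "p2", "p3"))
})

test_that("designated grains must be direct parts", {
  expect_error(buildModel(list(x = "T", y = "T", z = "T"),
                          list(c("x", "y"), c("y", "z")),
                          grainDesignation = list(x = "z")),
               "direct parts")
})

test_that("models round-trip through YAML and JSON documents", {
  wp <- makeWaterPortion(2L)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    writeModel(wp$model, path)
    back <- readModel(path)
    expect_setequal(entities(back), entities(wp$model))
    expect_setequal(properParts(back, wp$portion),
                    properParts(wp$model, wp$portion))
    expect_identical(back@instanceOf[["w1_mol"]], "Water_Molecule")
  }
})

test_that("model digests are stable and content-sensitive", {
  a <- makeMolecule("H2O")$model
  b <- makeMolecule("H2O")$model
  d <- makeMolecule("H2O2")$model
  expect_identical(modelDigest(a), modelDigest(b))
  expect_false(identical(modelDigest(a), modelDigest(d)))
})
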