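test_that("qualified cardinalities count typed role successors", {
  w <- makeMolecule("H2O")
  expect_identical(
    classExtension(exactlyN("has_component", 2, "H-Atom"), w$model,
                   w$registry),
    "mol")
  expect_identical(
    classExtension(exactlyN("has_component", 1, "O-Atom"), w$model,
                   w$registry),
    "mol")
  # universal restriction is vacuous without successors
  expect_true("h1" %in% classExtension(onlyValues("has_grain", "H-Atom"),
                                       w$model, w$registry))
  expect_error(classExtension(atomicClass("Nope"), w$model, w$registry),
               "undeclared class")
  expect_error(classExtension(someValues("part_of", "Atom"), w$model,
                              w$registry),
               "undeclared role")
})

test_that("atomic extensions close under the type hierarchy", {
  pr <- makeMolecule("N_propanol")
  expect_identical(
    classExtension(atomicClass("Propanol_Molecule"), pr$model, pr$registry),
    "mol")
  expect_identical(
    classExtension(atomicClass("Molecule"), pr$model, pr$registry), "mol")
  expect_length(
    classExtension(atomicClass("I-Propanol_Molecule"), pr$model,
                   pr$registry), 0L)
})

test_that("defined classes are evaluated through their equivalences", {
  wn <- makeWaterNested()
  tb <- tbox(collPattern("H-Atom"))
  expect_identical(
    classExtension(atomicClass("H-Atom_COLL"), wn$model, wn$registry, tb),
    "hp1")
  # cyclic definitions are refused, not looped
  tbBad <- tbox(list(equivalentTo("A", someValues("has_grain", "A"))))
  expect_error(classExtension(atomicClass("A"), wn$model, wn$registry,
                              tbBad),
               "cyclic class definition")
})

test_that("boolean structure matches set algebra on random models", {
  vocab <- c("A", "A1", "B", "C")
  reg <- typeRegistry(c("B", "C"), isA = list(c("A1", "A")))
  exprs <- list(
    a = atomicClass("A"), b = atomicClass("B"),
    s = someValues("has_grain", "A"),
    o = onlyValues("has_proper_part", "B"))
  for (seed in 1:40) {
    m <- randomModel(6L, vocab, seed = seed)
    ids <- entities(m)
    ext <- function(e) classExtension(e, m, reg)
    for (x in exprs) for (y in exprs) {
      expect_setequal(ext(andClass(x, y)), intersect(ext(x), ext(y)))
      expect_setequal(ext(orClass(x, y)), union(ext(x), ext(y)))
    }
    for (x in exprs)
      expect_setequal(ext(notClass(x)), setdiff(ids, ext(x)))
  }
})

test_that("exactly is the meet of min and max", {
  vocab <- c("A", "B")
  reg <- typeRegistry(vocab)
  for (seed in 1:25) {
    m <- randomModel(6L, vocab, seed = 100 + seed, edgeProb = 0.45)
    for (n in 1:3) {
      ex <- classExtension(exactlyN("has_component", n, "A"), m, reg)
      mn <- classExtension(minN("has_component", n, "A"), m, reg)
      mx <- classExtension(maxN("has_component", n, "A"), m, reg)
      expect_setequal(ex, intersect(mn, mx))
    }
  }
})

test_that("primitive mode sees only direct edges for the subroles", {
  wn <- makeWaterNested()
  # transitively, water has two H-atom parts; as direct components it has
  # none (they sit inside the pair)
  expect_setequal(
    classExtension(exactlyN("has_component", 2, "H-Atom"), wn$model,
                   wn$registry, mode = "fol"),
    c("water1", "hp1"))
  expect_identical(
    classExtension(exactlyN("has_component", 2, "H-Atom"), wn$model,
                   wn$registry, mode = "primitive"),
    "hp1")
})
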