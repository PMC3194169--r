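test_that("subsumption is reflexive and respects the hierarchy", {
  reg <- typeRegistry(c("Other"), isA = list(c("Cow", "Animal")))
  tb <- tbox()
  e <- someValues("has_grain", "Cow")
  v <- boundedSubsumption(tb, e, e, reg, maxSize = 3L)
  expect_true(v@holds)
  expect_gt(v@modelsChecked, 0L)

  v2 <- boundedSubsumption(tb, "Cow", "Animal", reg, maxSize = 3L)
  expect_true(v2@holds)
  v3 <- boundedSubsumption(tb, "Animal", "Cow", reg, maxSize = 3L)
  expect_false(v3@holds)
  expect_identical(v3@maxSizeChecked, 1L)  # a single entity suffices
})

test_that("countermodels genuinely witness the failure", {
  reg <- typeRegistry(c("Other"), isA = list(c("Cow", "Animal")))
  tb <- tbox()
  v <- boundedSubsumption(tb, someValues("has_grain", "Animal"),
                          someValues("has_grain", "Cow"), reg,
                          maxSize = 3L)
  expect_false(v@holds)
  cm <- v@countermodel
  expect_s4_class(cm, "FiniteModel")
  inSub <- classExtension(someValues("has_grain", "Animal"), cm, reg, tb)
  inSuper <- classExtension(someValues("has_grain", "Cow"), cm, reg, tb)
  expect_true(v@counterexample %in% inSub)
  expect_false(v@counterexample %in% inSuper)
})

test_that("the pair pattern entails exactly two grains", {
  reg <- typeRegistry(c("Kidney", "Other"))
  tb <- tbox(nCollPattern("Kidney", 2))
  v <- boundedSubsumption(tb, "Kidney_PAIR",
                          exactlyN("has_grain", 2, "Kidney"), reg,
                          maxSize = 4L)
  expect_true(v@holds)
  # and not three
  v3 <- boundedSubsumption(tb, "Kidney_PAIR",
                           exactlyN("has_grain", 3, "Kidney"), reg,
                           maxSize = 4L)
  expect_false(v3@holds)
})

test_that("disjointness axioms prune the admissible models", {
  reg <- typeRegistry(c("A", "B"))
  tb0 <- tbox()
  tb1 <- tbox(list(disjointWith(someValues("has_grain", "A"),
                                someValues("has_grain", "B"))))
  both <- andClass(someValues("has_grain", "A"), someValues("has_grain", "B"))
  # primitive reading: an entity may have an A and a B direct part
  expect_false(boundedSubsumption(tb0, both, notClass(both), reg,
                                  maxSize = 3L, mode = "primitive")@holds)
  # with the axiom, such an entity is inadmissible, so the absurd
  # subsumption holds vacuously
  expect_true(boundedSubsumption(tb1, both, notClass(both), reg,
                                 maxSize = 3L, mode = "primitive")@holds)
})

test_that("the resource guard caps enumeration with a partial verdict", {
  reg <- typeRegistry(c("A", "B"))
  v <- boundedSubsumption(tbox(), "A", "A", reg, maxSize = 4L,
                          maxModels = 10)
  expect_true(v@capped)
  expect_lte(v@modelsChecked, 10)
})

test_that("witness search returns the smallest satisfying model", {
  reg <- typeRegistry(c("Kidney", "Other"))
  tb <- tbox(nCollPattern("Kidney", 2))
  wit <- findMinimalWitness("Kidney_PAIR", tb, reg, maxSize = 4L)
  expect_length(entities(wit$model), 3L)  # the pair plus its two grains
  expect_length(grainsOf(wit$model, wit$entity), 2L)
  # nothing satisfies an unsatisfiable request within the bound
  expect_null(findMinimalWitness(andClass("Kidney", notClass("Kidney")),
                                 tb, reg, maxSize = 3L))
})

test_that("vocabulary must be declared", {
  reg <- typeRegistry("A")
  expect_error(boundedSubsumption(tbox(), "A", "A", reg, vocab = c("A", "Z")),
               "not declared")
})
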