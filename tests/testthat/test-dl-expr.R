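test_that("Manchester parsing follows the expected precedence", {
  e <- parseClassExpr("has_grain some H-Atom and has_grain only H-Atom")
  expect_identical(e@op, "and")
  expect_identical(e@args[[1L]]@op, "some")
  expect_identical(e@args[[2L]]@op, "only")
  expect_identical(e@args[[1L]]@role, "has_grain")

  # and binds tighter than or; restriction fillers are primaries
  e2 <- parseClassExpr("A and B or C")
  expect_identical(e2@op, "or")
  expect_identical(e2@args[[1L]]@op, "and")

  e3 <- parseClassExpr("r some A or B")
  expect_identical(e3@op, "or")
  expect_identical(e3@args[[1L]]@op, "some")

  e4 <- parseClassExpr("has_proper_part only (Propanol_Molecule or not (Molecule))")
  expect_identical(e4@op, "only")
  expect_identical(e4@args[[1L]]@op, "or")
  expect_identical(e4@args[[1L]]@args[[2L]]@op, "not")

  e5 <- parseClassExpr("has_grain exactly 2 H-Atom")
  expect_identical(e5@n, 2L)
})

test_that("syntax errors carry a character position", {
  expect_error(parseClassExpr("has_grain exactly 0 X"), "n >= 1")
  expect_error(parseClassExpr("A and"), "position")
  expect_error(parseClassExpr("A ++ B"), "position 3")
  expect_error(parseClassExpr("(A or B"), "expected '\\)'")
  expect_error(parseClassExpr("r exactly two X"), "cardinality")
})

test_that("render/parse round-trips are the identity", {
  cases <- list(
    atomicClass("H-Atom"),
    notClass("Molecule"),
    andClass("A", orClass("B", notClass("C"))),
    orClass(andClass("A", "B"), "C"),
    someValues("has_grain", orClass("N-Propanol_Molecule",
                                    "I-Propanol_Molecule")),
    onlyValues("has_proper_part",
               orClass(atomicClass("Propanol_COLL"),
                       someValues("proper_part_of", "Propanol_COLL"))),
    exactlyN("has_component", 2, "H-Atom"),
    andClass(exactlyN("has_component", 1, "O-Atom"),
             exactlyN("has_component", 2, "H-Atom"),
             onlyValues("has_component", orClass("H-Atom", "O-Atom"))),
    maxN("has_grain", 0, "Cow"),
    minN("has_grain", 3, notClass("Cow")))
  for (e in cases) {
    s <- renderClassExpr(e)
    expect_true(exprIdentical(parseClassExpr(s), e), info = s)
    # rendering is a normal form: parse o render is idempotent on strings
    expect_identical(renderClassExpr(parseClassExpr(s)), s)
  }
})

test_that("randomized expressions survive the round trip", {
  roles <- c("has_grain", "has_component", "has_proper_part")
  atoms <- c("A", "B-Type", "C_1")
  set.seed(42)
  randomExpr <- function(depth) {
    if (depth <= 0) return(atomicClass(sample(atoms, 1)))
    op <- sample(c("atom", "not", "and", "or", "some", "only", "exactly",
                   "min", "max"), 1)
    switch(op,
      atom = atomicClass(sample(atoms, 1)),
      not = notClass(randomExpr(depth - 1)),
      and = andClass(randomExpr(depth - 1), randomExpr(depth - 1)),
      or = orClass(randomExpr(depth - 1), randomExpr(depth - 1)),
      some = someValues(sample(roles, 1), randomExpr(depth - 1)),
      only = onlyValues(sample(roles, 1), randomExpr(depth - 1)),
      exactly = exactlyN(sample(roles, 1), sample(1:3, 1),
                         randomExpr(depth - 1)),
      min = minN(sample(roles, 1), sample(1:3, 1), randomExpr(depth - 1)),
      max = maxN(sample(roles, 1), sample(0:3, 1), randomExpr(depth - 1)))
  }
  for (i in 1:60) {
    e <- randomExpr(4)
    expect_true(exprIdentical(parseClassExpr(renderClassExpr(e)), e))
  }
})

test_that("constructors enforce arity and cardinality invariants", {
  expect_error(exactlyN("r", 0, "A"), "n >= 1")
  expect_error(minN("r", 0, "A"), "n >= 1")
  expect_s4_class(maxN("r", 0, "A"), "ClassExpr")
  expect_error(andClass("A"), ">= 2")
})
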