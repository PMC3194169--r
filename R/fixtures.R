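# Deterministic builders for the worked examples (molecules, portions,
# pairs, hands, herds, mixtures) and a seeded random-model generator.
# Molecule fixtures are composition-only: isomers share the atom multiset
# and differ by type label, since bond topology is out of scope here.

#' Shared type registry for the fixture catalogue
#'
#' Declares the atom and molecule hierarchy, body parts, and the
#' collective/pair types the fixtures use.
#' @return a [TypeRegistry-class]
#' @export
fixtureRegistry <- function() {
  reg <- typeRegistry(
    c("Atom", "Molecule", "Portion_of_Water", "Gas_Portion",
      "Portion_of_Blood_Plasma", "Kidney", "Organ_Pair", "Hand", "Basket",
      "Herd", "Cow", "Star", "Galaxy"),
    isA = list(
      c("H-Atom", "Atom"), c("O-Atom", "Atom"), c("C-Atom", "Atom"),
      c("Water_Molecule", "Molecule"),
      c("Hydrogen_Peroxide_Molecule", "Molecule"),
      c("Methanol_Molecule", "Molecule"),
      c("Ethanol_Molecule", "Molecule"),
      c("Oxygen_Molecule", "Molecule"),
      c("Ozone_Molecule", "Molecule"),
      c("Propanol_Molecule", "Molecule"),
      c("N-Propanol_Molecule", "Propanol_Molecule"),
      c("I-Propanol_Molecule", "Propanol_Molecule"),
      c("AlbuminMolecule", "PlasmaProteinMolecule"),
      c("GlobulinMolecule", "PlasmaProteinMolecule"),
      c("PlasmaProteinMolecule", "Molecule"),
      c("Finger", "Hand_Part"), c("Palm", "Hand_Part"),
      c("Apple", "Fruit"), c("Pear", "Fruit")),
    disjoint = list(c("N-Propanol_Molecule", "I-Propanol_Molecule")))
  registerNColl(reg, "H-Atom", 2L)
}

.MOLS <- list(
  H2O = list(type = "Water_Molecule",
             atoms = c(`O-Atom` = 1L, `H-Atom` = 2L)),
  H2O2 = list(type = "Hydrogen_Peroxide_Molecule",
              atoms = c(`O-Atom` = 2L, `H-Atom` = 2L)),
  N_propanol = list(type = "N-Propanol_Molecule",
                    atoms = c(`C-Atom` = 3L, `H-Atom` = 8L, `O-Atom` = 1L)),
  I_propanol = list(type = "I-Propanol_Molecule",
                    atoms = c(`C-Atom` = 3L, `H-Atom` = 8L, `O-Atom` = 1L)),
  methanol = list(type = "Methanol_Molecule",
                  atoms = c(`C-Atom` = 1L, `H-Atom` = 4L, `O-Atom` = 1L)),
  ethanol = list(type = "Ethanol_Molecule",
                 atoms = c(`C-Atom` = 2L, `H-Atom` = 6L, `O-Atom` = 1L)))

# type assignments + edges for one molecule, as plain lists
.moleculeParts <- function(kind, prefix) {
  info <- .MOLS[[kind]]
  if (is.null(info)) .stopf("unknown molecule kind '%s'", kind)
  mol <- paste0(prefix, "mol")
  types <- stats::setNames(list(info$type), mol)
  edges <- list()
  for (at in names(info$atoms)) {
    tag <- tolower(substr(sub("-Atom", "", at), 1L, 1L))
    for (i in seq_len(info$atoms[[at]])) {
      id <- paste0(prefix, tag, i)
      types[[id]] <- at
      edges <- c(edges, list(c(mol, id)))
    }
  }
  list(types = types, edges = edges, molecule = mol)
}

#' Build a canonical molecule fixture
#'
#' Flat composition models: the molecule entity with its atoms as direct
#' parts. `H2O` is one O plus two H atoms; `H2O2` two of each; the two
#' propanol isomers share the sum formula C3H8O and differ only in type
#' label; `methanol`/`ethanol` carry one- and two-carbon backbones.
#'
#' @param kind one of `"H2O"`, `"H2O2"`, `"N_propanol"`, `"I_propanol"`,
#'   `"methanol"`, `"ethanol"`.
#' @param prefix id prefix, for combining several molecules in one model.
#' @return list with `model` ([FiniteModel-class]), `registry`, and
#'   `molecule` (the molecule's entity id)
#' @examples
#' w <- makeMolecule("H2O")
#' properParts(w$model, w$molecule)
#' @export
makeMolecule <- function(kind, prefix = "") {
  p <- .moleculeParts(kind, prefix)
  list(model = buildModel(p$types, p$edges), registry = fixtureRegistry(),
       molecule = p$molecule)
}

#' Water molecule with an explicit hydrogen-pair component
#'
#' The nested spelling of water: one O atom plus one component that is a
#' strict pair collective of H atoms.
#' @return list with `model`, `registry`, ids `molecule` and `pair`
#' @export
makeWaterNested <- function() {
  m <- buildModel(
    list(water1 = "Water_Molecule", o1 = "O-Atom", hp1 = "H-Atom_PAIR",
         h1 = "H-Atom", h2 = "H-Atom"),
    list(c("water1", "o1"), c("water1", "hp1"),
         c("hp1", "h1"), c("hp1", "h2")))
  list(model = m, registry = fixtureRegistry(), molecule = "water1",
       pair = "hp1")
}

#' Portion of water with molecular and atomic granularity
#'
#' @param nMolecules number of water molecules in the portion (>= 1;
#'   one-molecule portions are legitimate singleton collectives).
#' @return list with `model`, `registry`, `portion` id
#' @export
makeWaterPortion <- function(nMolecules = 5L) {
  types <- list(portion1 = "Portion_of_Water")
  edges <- list()
  for (i in seq_len(nMolecules)) {
    p <- .moleculeParts("H2O", sprintf("w%d_", i))
    types <- c(types, p$types)
    edges <- c(edges, list(c("portion1", p$molecule)), p$edges)
  }
  list(model = buildModel(types, edges), registry = fixtureRegistry(),
       portion = "portion1")
}

#' Hand with a configurable number of fingers
#'
#' Canonical hands have five fingers; four- and six-fingered hands are
#' still hands (the type is flexible about the count).
#' @param nFingers number of fingers (default 5).
#' @return list with `model`, `registry`, `hand` id, and `spec`
#'   (fingers at least one, palm unconstrained)
#' @export
makeHand <- function(nFingers = 5L) {
  types <- list(hand1 = "Hand", palm1 = "Palm")
  edges <- list(c("hand1", "palm1"))
  for (i in seq_len(nFingers)) {
    id <- paste0("f", i)
    types[[id]] <- "Finger"
    edges <- c(edges, list(c("hand1", id)))
  }
  list(model = buildModel(types, edges), registry = fixtureRegistry(),
       hand = "hand1",
       spec = typeSpec("Hand", list(atLeast("Finger", 1L),
                                    anyNumber("Palm")), closed = FALSE))
}

#' The Table of exemplars: one fixture per kind of complex entity
#'
#' Builds the canonical examples for the four categories plus the
#' granularity/specificity fixtures: a portion of water (flexible
#' collective), a pair of kidneys (strict collective), a hand (flexible
#' compound), a propanol molecule (strict compound), the galaxy/star/
#' molecule chain (non-transitivity), the fruit basket (specificity), the
#' O2/O3 gas mixture (granularity), a blood-plasma sample and a herd.
#'
#' Each entry carries `model`, the `focus` entity, and where a
#' classification is meaningful also `spec` and `level`.
#'
#' @return list with `registry` and named fixture entries
#' @export
makeExemplars <- function() {
  reg <- fixtureRegistry()
  out <- list(registry = reg)

  wp <- makeWaterPortion(5L)
  out$portion_of_water <- list(
    model = wp$model, focus = wp$portion, level = "Molecule",
    spec = typeSpec("Portion_of_Water",
                    list(atLeast("Water_Molecule", 1L)), closed = TRUE))

  out$pair_of_kidneys <- list(
    model = buildModel(list(kpair1 = "Organ_Pair", k1 = "Kidney",
                            k2 = "Kidney"),
                       list(c("kpair1", "k1"), c("kpair1", "k2"))),
    focus = "kpair1", level = "Kidney",
    spec = typeSpec("Pair_of_Kidneys", list(exactly("Kidney", 2L)),
                    closed = TRUE))

  hand <- makeHand(5L)
  out$hand <- list(model = hand$model, focus = hand$hand,
                   level = "Hand_Part", spec = hand$spec)

  pr <- makeMolecule("N_propanol")
  out$propanol_molecule <- list(
    model = pr$model, focus = pr$molecule, level = "Atom",
    spec = typeSpec("Propanol_Molecule",
                    list(exactly("C-Atom", 3L), exactly("H-Atom", 8L),
                         exactly("O-Atom", 1L)), closed = TRUE))

  out$galaxy <- list(
    model = buildModel(
      list(galaxy1 = "Galaxy", s1 = "Star", s2 = "Star",
           m1 = "Molecule", m2 = "Molecule", m3 = "Molecule"),
      list(c("galaxy1", "s1"), c("galaxy1", "s2"),
           c("s1", "m1"), c("s1", "m2"), c("s2", "m3"))),
    focus = "galaxy1")

  out$fruit_basket <- list(
    model = buildModel(list(basket1 = "Basket", a1 = "Apple", p1 = "Pear"),
                       list(c("basket1", "a1"), c("basket1", "p1"))),
    focus = "basket1", level = "Fruit")

  o2 <- list(types = list(gas1 = "Gas_Portion", om1 = "Oxygen_Molecule",
                          zm1 = "Ozone_Molecule"),
             edges = list(c("gas1", "om1"), c("gas1", "zm1")))
  for (i in 1:2) {
    id <- paste0("oa", i); o2$types[[id]] <- "O-Atom"
    o2$edges <- c(o2$edges, list(c("om1", id)))
  }
  for (i in 3:5) {
    id <- paste0("oa", i); o2$types[[id]] <- "O-Atom"
    o2$edges <- c(o2$edges, list(c("zm1", id)))
  }
  out$o2_o3_mixture <- list(model = buildModel(o2$types, o2$edges),
                            focus = "gas1", level = "Molecule")

  out$blood_plasma <- list(
    model = buildModel(
      list(plasma1 = "Portion_of_Blood_Plasma", al1 = "AlbuminMolecule",
           al2 = "AlbuminMolecule", gl1 = "GlobulinMolecule"),
      list(c("plasma1", "al1"), c("plasma1", "al2"), c("plasma1", "gl1"))),
    focus = "plasma1", level = "PlasmaProteinMolecule")

  out$herd <- list(
    model = buildModel(list(herd1 = "Herd", c1 = "Cow", c2 = "Cow",
                            c3 = "Cow"),
                       list(c("herd1", "c1"), c("herd1", "c2"),
                            c("herd1", "c3"))),
    focus = "herd1", level = "Cow")

  out$hand_4 <- { h <- makeHand(4L); list(model = h$model, focus = h$hand,
                                          level = "Hand_Part", spec = h$spec) }
  out$hand_6 <- { h <- makeHand(6L); list(model = h$model, focus = h$hand,
                                          level = "Hand_Part", spec = h$spec) }
  out$water_portion_singleton <- {
    w <- makeWaterPortion(1L)
    list(model = w$model, focus = w$portion, level = "Molecule",
         spec = out$portion_of_water$spec)
  }
  out
}

#' Seeded random finite model
#'
#' Acyclic random part-graph with random type labels; deterministic per
#' seed (the global RNG state is saved and restored).
#'
#' @param nEntities number of entities (>= 0).
#' @param vocab type names to sample labels from.
#' @param seed integer seed.
#' @param edgeProb probability of each forward edge (default 0.3).
#' @return a [FiniteModel-class]
#' @export
randomModel <- function(nEntities, vocab, seed, edgeProb = 0.3) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (nEntities == 0L) return(buildModel())
  ids <- paste0("r", seq_len(nEntities))
  types <- lapply(ids, function(i)
    sample(vocab, sample(1:2, 1L), replace = FALSE))
  names(types) <- ids
  edges <- list()
  if (nEntities >= 2L)
    for (j in 2:nEntities)
      for (i in seq_len(j - 1L))
        if (stats::runif(1L) < edgeProb)
          edges <- c(edges, list(c(ids[i], ids[j])))
  buildModel(types, if (length(edges)) edges else NULL)
}
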