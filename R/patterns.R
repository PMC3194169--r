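# Compilers from mereological design patterns to OWL class axioms. Every
# generated axiom carries a provenance tag naming its pattern, so a built
# ontology can be audited pattern by pattern.

#' Assemble an ontology
#'
#' @param name ontology name (used in the IRI on emission).
#' @param registry a [TypeRegistry-class] holding the atomic hierarchy.
#' @param axioms list of [Axiom-class] objects.
#' @return an [Ontology-class]; declared classes are the registry's types
#'   plus every atomic name mentioned in an axiom
#' @export
ontology <- function(name, registry, axioms = list()) {
  cls <- unique(c(registry@typeTable$name,
                  unlist(lapply(axioms, function(a)
                    c(.exprAtoms(a@lhs), .exprAtoms(a@rhs))))))
  new("Ontology", name = name, classes = sort(cls),
      tbox = tbox(axioms = axioms), registry = registry)
}

.axiomKey <- function(a)
  paste(a@type, renderClassExpr(a@lhs), renderClassExpr(a@rhs), sep = " | ")

#' Add axioms to an ontology, skipping duplicates
#'
#' Re-applying a pattern is idempotent: an axiom whose type and both sides
#' already occur is not added again.
#' @param ont an [Ontology-class].
#' @param axs list of [Axiom-class] objects.
#' @return the extended ontology
#' @export
addAxioms <- function(ont, axs) {
  have <- vapply(ont@tbox@axioms, .axiomKey, character(1))
  for (a in axs) {
    k <- .axiomKey(a)
    if (!k %in% have) {
      ont@tbox <- initialize(ont@tbox, axioms = c(ont@tbox@axioms, list(a)))
      have <- c(have, k)
    }
  }
  ont@classes <- sort(unique(c(ont@classes,
                               unlist(lapply(axs, function(a)
                                 c(.exprAtoms(a@lhs), .exprAtoms(a@rhs)))))))
  ont
}

#' Select a TBox by relation regime
#'
#' The grain regime formulates classes through the primitive subroles
#' `has_grain`/`has_component`; the proper-part regime through
#' `has_proper_part`/`proper_part_of` only. The two regimes give the same
#' class names different definitions, so the oracle loads one at a time;
#' `"common"` axioms (hierarchy, disjointness) are always included.
#'
#' @param ont an [Ontology-class].
#' @param regime `"grain"` or `"proper_part"`.
#' @return a [TBox-class]
#' @export
tboxFor <- function(ont, regime = c("proper_part", "grain")) {
  regime <- match.arg(regime)
  keep <- vapply(ont@tbox@axioms, function(a)
    a@regime %in% c("common", regime), logical(1))
  initialize(ont@tbox, axioms = ont@tbox@axioms[keep])
}

#' Collective design pattern
#'
#' Defines `Base_COLL` (or `name`) as the class of entities with some grain
#' of the base type and only grains of the base type.
#'
#' @param base grain type name.
#' @param name collective class name; defaults to [collName()] of `base`.
#' @return list of [Axiom-class]
#' @examples
#' collPattern("H-Atom")
#' @export
collPattern <- function(base, name = collName(base)) {
  list(equivalentTo(
    name,
    andClass(someValues("has_grain", base), onlyValues("has_grain", base)),
    provenance = sprintf("pattern:coll(%s)", base), regime = "grain"))
}

#' Strict n-collective design pattern
#'
#' Defines the class of collectives of exactly `n` grains of the base type:
#' `Base_COLL and has_grain exactly n Base and has_grain only Base`. The
#' case `n = 2` is the pair pattern. The referenced `Base_COLL` definition
#' is emitted alongside.
#'
#' @inheritParams collPattern
#' @param n grain count, `n >= 1`.
#' @param name n-collective class name; defaults to [nCollName()].
#' @param collClassName name of the referenced collective class; defaults
#'   to [collName()] of `base`.
#' @return list of [Axiom-class]
#' @export
nCollPattern <- function(base, n, name = nCollName(base, n),
                         collClassName = collName(base)) {
  if (n < 1L) .stopf("an n-collective needs n >= 1, got %d", n)
  c(collPattern(base, collClassName),
    list(equivalentTo(
      name,
      andClass(atomicClass(collClassName),
               exactlyN("has_grain", n, base),
               onlyValues("has_grain", base)),
      provenance = sprintf("pattern:n-coll(%s,%d)", base, n),
      regime = "grain")))
}

#' Molecule composition design pattern
#'
#' Renders a fixed atomic composition as class axioms, in one of three
#' spellings:
#' \describe{
#'   \item{`flat`}{`has_component exactly n_i A_i` per atom type plus the
#'     closure conjunct `has_component only (A_1 or ... or A_k)`.}
#'   \item{`nested`}{atom types with count one as components, atom types
#'     with larger counts as one component that is a strict collective of
#'     that count (pair etc.), plus the collective definitions.}
#'   \item{`proper_part`}{the same counts through the transitive
#'     `has_proper_part` with closure
#'     `only (A_1 or ... or not Atom)` -- deliberately outside OWL DL,
#'     [isDLSafe()] flags every cardinality node.}
#' }
#'
#' @param name molecule class name.
#' @param composition named integer vector, atom type -> count (>= 1).
#' @param variant `"flat"`, `"nested"` or `"proper_part"`.
#' @param guard granularity guard type for the `proper_part` closure
#'   (default `"Atom"`).
#' @return list of [Axiom-class]
#' @examples
#' moleculePattern("Water_Molecule", c(`O-Atom` = 1, `H-Atom` = 2), "flat")
#' @export
moleculePattern <- function(name, composition,
                            variant = c("flat", "nested", "proper_part"),
                            guard = "Atom") {
  variant <- match.arg(variant)
  if (any(composition < 1L)) .stopf("atom counts must be >= 1")
  atoms <- names(composition)
  orAtoms <- function(extra = NULL) {
    args <- c(lapply(atoms, atomicClass), extra)
    if (length(args) == 1L) args[[1L]] else do.call(orClass, args)
  }
  if (variant == "flat") {
    conj <- c(lapply(atoms, function(a)
                exactlyN("has_component", composition[[a]], a)),
              list(onlyValues("has_component", orAtoms())))
    list(subClassOf(name, do.call(andClass, conj),
                    provenance = sprintf("pattern:molecule-flat(%s)", name),
                    regime = "grain"))
  } else if (variant == "nested") {
    out <- list()
    conj <- list()
    for (a in atoms) {
      cnt <- composition[[a]]
      if (cnt == 1L) {
        conj <- c(conj, list(exactlyN("has_component", 1L, a)))
      } else {
        out <- c(out, collPattern(a))
        conj <- c(conj, list(exactlyN(
          "has_component", 1L,
          andClass(atomicClass(collName(a)),
                   exactlyN("has_grain", cnt, a)))))
      }
    }
    c(out, list(subClassOf(
      name, do.call(andClass, conj),
      provenance = sprintf("pattern:molecule-nested(%s)", name),
      regime = "grain")))
  } else {
    conj <- c(lapply(atoms, function(a)
                exactlyN("has_proper_part", composition[[a]], a)),
              list(onlyValues("has_proper_part",
                              orAtoms(list(notClass(guard))))))
    list(subClassOf(name, do.call(andClass, conj),
                    provenance = sprintf("pattern:molecule-proper-part(%s)",
                                         name),
                    regime = "proper_part"))
  }
}

#' Flexible compound design pattern
#'
#' `name subClassOf has_component some ComponentColl`: a hand has some
#' collective of fingers as a component, whatever their number.
#'
#' @param name compound class name.
#' @param componentColl name of a collective class generated by
#'   [collPattern()]; a name without the collective suffix triggers a
#'   pattern-misuse warning.
#' @return list of [Axiom-class]
#' @export
flexibleCompoundPattern <- function(name, componentColl) {
  if (!grepl("(_COLL|_PAIR)$", componentColl))
    warning(sprintf(
      "'%s' does not look like a collective class; expected a _COLL name",
      componentColl), call. = FALSE)
  list(subClassOf(name, someValues("has_component", componentColl),
                  provenance = sprintf("pattern:flexible-compound(%s)", name),
                  regime = "grain"))
}

#' Fraction specification for a mixture
#'
#' A mixture is a compound of fractions, each fraction a collective of
#' grains of one sort.
#'
#' @param fractions list of `c(grain = type, coll = collectiveClassName)`
#'   entries, at least two, with pairwise distinct grain types.
#' @param closureType most specific common supertype of the grain types
#'   (e.g. `Propanol_Molecule`).
#' @param guard granularity guard (e.g. `Molecule`): the closure conjunct
#'   constrains parts of this sort only.
#' @param closureColl name of the collective class of `closureType`.
#' @return a `FractionSpec` list used by [mixturePattern()]
#' @export
fractionSpec <- function(fractions, closureType, guard,
                         closureColl = collName(closureType)) {
  if (length(fractions) < 2L)
    .stopf("a mixture needs at least 2 fractions, got %d", length(fractions))
  grains <- vapply(fractions, function(f) f[["grain"]], character(1))
  if (anyDuplicated(grains)) .stopf("fraction grain types must be distinct")
  structure(list(fractions = lapply(fractions, as.list),
                 closureType = closureType, guard = guard,
                 closureColl = closureColl),
            class = "FractionSpec")
}

#' Mixture design patterns
#'
#' Four ways to represent a mixture of several grain sorts:
#' \describe{
#'   \item{`grain_disjunction`}{`has_grain some (G1 or G2 or ...)` --
#'     simple, but weakens the uniformity of grainhood.}
#'   \item{`supertype`}{`has_grain some ClosureType` -- describes the
#'     grains at the common supertype only.}
#'   \item{`fraction_compound`}{a compound of fraction collectives:
#'     `has_component some G1_COLL and ... and has_component only
#'     (ClosureColl or not Guard)`; the fraction collective definitions are
#'     emitted alongside.}
#'   \item{`reasoner_friendly`}{the same content through
#'     `has_proper_part`/`proper_part_of` only (no `has_grain` or
#'     `has_component` symbol occurs): the mixture holds some part of each
#'     grain sort and every part is either a closure collective or a proper
#'     part of one; the collective itself is defined as having some part of
#'     the closure type and only parts that are of the closure type or not
#'     of the guard sort. In this spelling a DL classifier can compute
#'     mixture-under-collective subsumption.}
#' }
#'
#' @param name mixture class name.
#' @param spec a [fractionSpec()].
#' @param variant one of the four variants.
#' @return list of [Axiom-class]
#' @export
mixturePattern <- function(name, spec,
                           variant = c("grain_disjunction", "supertype",
                                       "fraction_compound",
                                       "reasoner_friendly")) {
  variant <- match.arg(variant)
  stopifnot(inherits(spec, "FractionSpec"))
  grains <- vapply(spec$fractions, function(f) f$grain, character(1))
  colls <- vapply(spec$fractions, function(f) f$coll, character(1))
  grainDisj <- do.call(orClass, lapply(grains, atomicClass))
  switch(variant,
    grain_disjunction = list(subClassOf(
      name, someValues("has_grain", grainDisj),
      provenance = sprintf("pattern:mixture-grain-disjunction(%s)", name),
      regime = "grain")),
    supertype = list(subClassOf(
      name, someValues("has_grain", spec$closureType),
      provenance = sprintf("pattern:mixture-supertype(%s)", name),
      regime = "grain")),
    fraction_compound = c(
      unlist(lapply(seq_along(grains), function(i)
        collPattern(grains[i], colls[i])), recursive = FALSE),
      collPattern(spec$closureType, spec$closureColl),
      list(equivalentTo(
        name,
        do.call(andClass, c(
          lapply(colls, function(cc) someValues("has_component", cc)),
          list(onlyValues("has_component",
                          orClass(atomicClass(spec$closureColl),
                                  notClass(spec$guard)))))),
        provenance = sprintf("pattern:mixture-fraction-compound(%s)", name),
        regime = "grain"))),
    reasoner_friendly = list(
      equivalentTo(
        spec$closureColl,
        andClass(someValues("has_proper_part", spec$closureType),
                 onlyValues("has_proper_part",
                            orClass(atomicClass(spec$closureType),
                                    notClass(spec$guard)))),
        provenance = sprintf("pattern:collective-proper-part(%s)",
                             spec$closureColl),
        regime = "proper_part"),
      equivalentTo(
        name,
        do.call(andClass, c(
          lapply(grains, function(g) someValues("has_proper_part", g)),
          list(onlyValues("has_proper_part",
                          orClass(atomicClass(spec$closureColl),
                                  someValues("proper_part_of",
                                             spec$closureColl)))))),
        provenance = sprintf("pattern:mixture-reasoner-friendly(%s)", name),
        regime = "proper_part")))
}

#' Catalogue ontology exercising every design pattern
#'
#' Builds one ontology containing the worked examples: water and hydrogen
#' peroxide molecules in all three molecule spellings, the hydrogen pair
#' and kidney pair, hand and alcohol flexible compounds, the blood-plasma
#' mixture in the grain-disjunction, supertype and fraction-compound
#' spellings, and the full propanol mixture block. Useful for auditing
#' provenance coverage and DL safety across patterns.
#'
#' @return an [Ontology-class]
#' @export
buildPatternLibrary <- function() {
  reg <- typeRegistry(
    c("Atom", "Molecule", "Kidney", "Finger", "Hand", "Alcohol_Molecule"),
    isA = list(
      c("H-Atom", "Atom"), c("O-Atom", "Atom"), c("C-Atom", "Atom"),
      c("Water_Molecule", "Molecule"),
      c("Hydrogen_Peroxide_Molecule", "Molecule"),
      c("AlbuminMolecule", "PlasmaProteinMolecule"),
      c("GlobulinMolecule", "PlasmaProteinMolecule"),
      c("PlasmaProteinMolecule", "Molecule"),
      c("Propanol_Molecule", "Molecule"),
      c("N-Propanol_Molecule", "Propanol_Molecule"),
      c("I-Propanol_Molecule", "Propanol_Molecule")),
    disjoint = list(c("N-Propanol_Molecule", "I-Propanol_Molecule"),
                    c("AlbuminMolecule", "GlobulinMolecule")))
  hier <- c(
    lapply(seq_len(nrow(reg@isA)), function(k)
      subClassOf(reg@isA[k, 1L], reg@isA[k, 2L],
                 provenance = "pattern:hierarchy", regime = "common")),
    lapply(seq_len(nrow(reg@disjoint)), function(k)
      disjointWith(reg@disjoint[k, 1L], reg@disjoint[k, 2L],
                   provenance = "pattern:disjointness", regime = "common")))
  water <- c(`O-Atom` = 1L, `H-Atom` = 2L)
  plasma <- fractionSpec(
    list(c(grain = "AlbuminMolecule", coll = "Albumin_COLL"),
         c(grain = "GlobulinMolecule", coll = "Globulin_COLL")),
    closureType = "PlasmaProteinMolecule", guard = "Molecule",
    closureColl = "PlasmaProtein_COLL")
  ont <- ontology("pattern-library", reg, hier)
  for (axs in list(
    moleculePattern("Water_Molecule", water, "flat"),
    moleculePattern("Water_Molecule", water, "nested"),
    moleculePattern("Water_Molecule", water, "proper_part"),
    moleculePattern("Hydrogen_Peroxide_Molecule",
                    c(`O-Atom` = 2L, `H-Atom` = 2L), "flat"),
    nCollPattern("H-Atom", 2L),
    nCollPattern("Kidney", 2L),
    collPattern("Finger"),
    collPattern("C-Atom", "C_COLL"),
    flexibleCompoundPattern("Hand", "Finger_COLL"),
    flexibleCompoundPattern("Alcohol_Molecule", "C_COLL"),
    mixturePattern("BloodPlasmaSample", plasma, "grain_disjunction"),
    mixturePattern("BloodPlasmaSample", plasma, "supertype"),
    mixturePattern("BloodPlasmaSample", plasma, "fraction_compound")))
    ont <- addAxioms(ont, axs)
  propanol <- buildPropanolOntology()
  addAxioms(ont, propanol@tbox@axioms)
}
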