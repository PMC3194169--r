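# The propanol disinfectant use case: one molecule type with two isomers
# (same sum formula C3H8O, distinguished here by label only), three mixture
# representation variants, and the reasoner-friendly rewrite under which
# all three are classified as propanol collectives.

#' Type registry for the propanol use case
#'
#' `Molecule > Propanol_Molecule > {N-Propanol_Molecule,
#' I-Propanol_Molecule}` with the isomers disjoint, plus a
#' `Portion_of_Matter` type standing for non-molecular entities in
#' enumerated models.
#' @return a [TypeRegistry-class]
#' @export
propanolRegistry <- function() {
  typeRegistry(
    c("Molecule", "Portion_of_Matter"),
    isA = list(c("Propanol_Molecule", "Molecule"),
               c("N-Propanol_Molecule", "Propanol_Molecule"),
               c("I-Propanol_Molecule", "Propanol_Molecule")),
    disjoint = list(c("N-Propanol_Molecule", "I-Propanol_Molecule")))
}

#' Regenerate the propanol mixture ontology
#'
#' Builds the sample ontology of the propanol use case: the molecule
#' hierarchy with disjoint isomers; grain-regime collective classes for
#' propanol and each isomer; three mixture representation variants
#' (`Propanol_Mixture_1` grain disjunction, `Propanol_Mixture_2` grain
#' supertype, `Propanol_Mixture_3` compound of fraction collectives), each
#' with its primitive-subrole axiom and its proper-part rewrite; and the
#' proper-part collective definition of `Propanol_COLL`. Under the
#' proper-part regime all three mixture variants are entailed subclasses of
#' `Propanol_COLL` (checked by [propanolSubsumptions()]).
#'
#' @param collectiveMoleculeDisjoint assert that no molecule is itself a
#'   propanol collective (default `TRUE`). Without this axiom the
#'   mixture-under-collective subsumption fails: a non-propanol molecule
#'   all of whose proper parts are propanol molecules would satisfy the
#'   collective definition, may sit inside a mixture, and then violates the
#'   collective's closure. With it, the subsumption holds in every
#'   enumerated model.
#' @return an [Ontology-class]
#' @export
buildPropanolOntology <- function(collectiveMoleculeDisjoint = TRUE) {
  reg <- propanolRegistry()
  hier <- c(
    lapply(seq_len(nrow(reg@isA)), function(k)
      subClassOf(reg@isA[k, 1L], reg@isA[k, 2L],
                 provenance = "pattern:hierarchy", regime = "common")),
    list(disjointWith("N-Propanol_Molecule", "I-Propanol_Molecule",
                      provenance = "pattern:isomer-disjointness",
                      regime = "common")))
  spec <- propanolFractionSpec()
  ont <- ontology("propanol", reg, hier)
  ont <- addAxioms(ont, collPattern("Propanol_Molecule", "Propanol_COLL"))
  ont <- addAxioms(ont, collPattern("N-Propanol_Molecule", "N-Propanol_COLL"))
  ont <- addAxioms(ont, collPattern("I-Propanol_Molecule", "I-Propanol_COLL"))
  # primitive-subrole formulations of the three variants
  ont <- addAxioms(ont, mixturePattern("Propanol_Mixture_1", spec,
                                       "grain_disjunction"))
  ont <- addAxioms(ont, mixturePattern("Propanol_Mixture_2", spec,
                                       "supertype"))
  ont <- addAxioms(ont, mixturePattern("Propanol_Mixture_3", spec,
                                       "fraction_compound"))
  # proper-part rewrites: collective definition plus mixture 3
  ont <- addAxioms(ont, mixturePattern("Propanol_Mixture_3", spec,
                                       "reasoner_friendly"))
  # rewrites of variants 1 and 2 in the same role regime
  closure13 <- onlyValues("has_proper_part",
                          orClass(atomicClass("Propanol_Molecule"),
                                  notClass("Molecule")))
  ont <- addAxioms(ont, list(
    equivalentTo("Propanol_Mixture_1",
                 andClass(someValues("has_proper_part",
                                     orClass(atomicClass("N-Propanol_Molecule"),
                                             atomicClass("I-Propanol_Molecule"))),
                          closure13),
                 provenance = "pattern:mixture-reasoner-friendly(Propanol_Mixture_1)",
                 regime = "proper_part"),
    equivalentTo("Propanol_Mixture_2",
                 andClass(someValues("has_proper_part", "Propanol_Molecule"),
                          closure13),
                 provenance = "pattern:mixture-reasoner-friendly(Propanol_Mixture_2)",
                 regime = "proper_part")))
  if (collectiveMoleculeDisjoint)
    ont <- addAxioms(ont, list(
      disjointWith("Propanol_COLL", "Molecule",
                   provenance = "pattern:collective-molecule-disjointness",
                   regime = "proper_part")))
  ont
}

#' @rdname buildPropanolOntology
#' @export
propanolFractionSpec <- function() {
  fractionSpec(
    list(c(grain = "N-Propanol_Molecule", coll = "N-Propanol_COLL"),
         c(grain = "I-Propanol_Molecule", coll = "I-Propanol_COLL")),
    closureType = "Propanol_Molecule", guard = "Molecule",
    closureColl = "Propanol_COLL")
}

#' Mixture-under-collective subsumption checks for the propanol ontology
#'
#' Runs the bounded oracle on the proper-part regime of the ontology:
#' is each of the three mixture variants subsumed by `Propanol_COLL`?
#'
#' @param ont ontology from [buildPropanolOntology()].
#' @param maxSize bound for the model enumeration (default 4).
#' @param maxModels resource guard passed to [boundedSubsumption()].
#' @return named list of [Verdict-class], one per mixture variant
#' @export
propanolSubsumptions <- function(ont = buildPropanolOntology(),
                                 maxSize = 4L, maxModels = 5e6) {
  tb <- tboxFor(ont, "proper_part")
  vocab <- c("N-Propanol_Molecule", "I-Propanol_Molecule", "Molecule",
             "Portion_of_Matter")
  out <- list()
  for (m in c("Propanol_Mixture_1", "Propanol_Mixture_2",
              "Propanol_Mixture_3"))
    out[[m]] <- boundedSubsumption(tb, m, "Propanol_COLL", ont@registry,
                                   vocab = vocab, maxSize = maxSize,
                                   maxModels = maxModels)
  out
}

#' Negative control: the primitive-subrole mixture is not classified
#'
#' With `has_grain` and `has_component` taken as bare primitive subroles
#' (all a DL reasoner can see of them), the fraction-compound mixture
#' definition does not entail the grain-based collective definition: the
#' oracle produces a countermodel, typically a mixture whose direct parts
#' are the two fraction collectives rather than propanol molecules.
#'
#' @inheritParams propanolSubsumptions
#' @param maxSize bound for the countermodel search (default 5; the
#'   expected countermodel has five entities).
#' @return a [Verdict-class] (expected: `holds = FALSE`)
#' @export
propanolNegativeControl <- function(ont = buildPropanolOntology(),
                                    maxSize = 5L, maxModels = 5e6) {
  tb <- tboxFor(ont, "grain")
  vocab <- c("N-Propanol_Molecule", "I-Propanol_Molecule", "Portion_of_Matter")
  boundedSubsumption(tb, "Propanol_Mixture_3", "Propanol_COLL",
                     ont@registry, vocab = vocab, maxSize = maxSize,
                     mode = "primitive", maxModels = maxModels)
}
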