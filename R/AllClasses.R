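#' @import methods
NULL

#' Registry of named types
#'
#' A `TypeRegistry` holds the type vocabulary a finite model is labelled
#' from: plain named types, derived collective types (`X_COLL`, collectives
#' whose grains instantiate `X`) and derived n-collective types (strict
#' collectives with a fixed grain count), an acyclic `is_a` hierarchy, and
#' pairwise disjointness axioms. Subsumption queries use the
#' reflexive-transitive closure of `is_a`.
#'
#' @slot typeTable data.frame with columns `name`, `kind`
#'   (`"plain"`, `"coll"`, `"ncoll"`), `base` (base type for derived kinds,
#'   else `NA`) and `n` (grain count for `"ncoll"`, else `NA`).
#' @slot isA two-column character matrix of (child, parent) edges.
#' @slot disjoint two-column character matrix of unordered disjoint pairs.
#' @export
setClass("TypeRegistry",
  representation(typeTable = "data.frame", isA = "matrix", disjoint = "matrix"),
  validity = function(object) {
    tt <- object@typeTable
    if (!all(c("name", "kind", "base", "n") %in% names(tt)))
      return("typeTable must have columns name, kind, base, n")
    if (anyDuplicated(tt$name)) return("duplicate type names")
    if (!all(tt$kind %in% c("plain", "coll", "ncoll")))
      return("kind must be plain, coll or ncoll")
    bad <- tt$kind == "ncoll" & (is.na(tt$n) | tt$n < 1L)
    if (any(bad)) return("ncoll types need n >= 1")
    for (m in list(object@isA, object@disjoint))
      if (ncol(m) != 2L) return("isA/disjoint must have two columns")
    known <- tt$name
    ref <- c(object@isA, object@disjoint, tt$base[!is.na(tt$base)])
    if (!all(ref %in% known)) return(sprintf(
      "undeclared type '%s' referenced", setdiff(ref, known)[1L]))
    if (nrow(object@isA)) {
      ids <- known
      e <- cbind(match(object@isA[, 1L], ids), match(object@isA[, 2L], ids))
      if (.findCycleNode(e, length(ids)) > 0L) return("is_a hierarchy is cyclic")
    }
    # a disjoint pair must not also sit on one is_a chain
    if (nrow(object@disjoint)) {
      for (k in seq_len(nrow(object@disjoint))) {
        a <- object@disjoint[k, 1L]; b <- object@disjoint[k, 2L]
        up <- .ancestorsOf(object)
        if (b %in% up[[a]] || a %in% up[[b]] || a == b)
          return(sprintf("'%s' and '%s' are disjoint yet is_a-related", a, b))
      }
    }
    TRUE
  })

#' Finite instance model of mereological reality
#'
#' Entities with type labels and an acyclic direct-parthood graph. The
#' transitive closure of `directPart` interprets `has_proper_part`; candidate
#' grains of an entity default to its direct parts unless a designation is
#' recorded.
#'
#' @slot entities character vector of unique entity ids.
#' @slot instanceOf named list mapping each entity to a non-empty character
#'   vector of asserted type names.
#' @slot directPart two-column character matrix of (whole, part) edges.
#' @slot grainDesignation named list mapping an entity to the subset of its
#'   direct parts designated as its grains (optional, may be empty).
#' @export
setClass("FiniteModel",
  representation(entities = "character", instanceOf = "list",
                 directPart = "matrix", grainDesignation = "list"),
  validity = function(object) {
    ids <- object@entities
    if (anyDuplicated(ids)) return(sprintf(
      "duplicate entity id '%s'", ids[duplicated(ids)][1L]))
    if (ncol(object@directPart) != 2L) return("directPart must have 2 columns")
    mentioned <- c(object@directPart,
                   names(object@grainDesignation),
                   unlist(object@grainDesignation, use.names = FALSE),
                   names(object@instanceOf))
    unknown <- setdiff(mentioned, ids)
    if (length(unknown)) return(sprintf("unknown entity '%s'", unknown[1L]))
    if (length(ids)) {
      if (!setequal(names(object@instanceOf), ids))
        return("every entity needs an instanceOf entry")
      if (any(lengths(object@instanceOf) == 0L))
        return("instanceOf entries must be non-empty")
    }
    if (nrow(object@directPart)) {
      e <- cbind(match(object@directPart[, 1L], ids),
                 match(object@directPart[, 2L], ids))
      cyc <- .findCycleNode(e, length(ids))
      if (cyc > 0L) return(sprintf(
        "parthood cycle through entity '%s'", ids[cyc]))
    }
    for (x in names(object@grainDesignation)) {
      dp <- object@directPart[object@directPart[, 1L] == x, 2L]
      if (!all(object@grainDesignation[[x]] %in% dp))
        return(sprintf("designated grains of '%s' are not direct parts", x))
    }
    TRUE
  })

#' Partition of a whole into segments
#'
#' A candidate decomposition of `whole` into pairwise disjoint, jointly
#' exhaustive segments; validity against a model is checked by
#' [isValidPartition()]. Segments are compared as sets, order is irrelevant.
#'
#' @slot whole entity id of the compound.
#' @slot segments character vector of segment entity ids (length >= 1).
#' @export
setClass("Partition",
  representation(whole = "character", segments = "character"),
  validity = function(object) {
    if (length(object@whole) != 1L) return("whole must be a single entity id")
    if (length(object@segments) < 1L) return("a partition needs >= 1 segment")
    TRUE
  })

#' Composition specification for the four-way classifier
#'
#' Cardinality constraints per component type, used to decide whether the
#' number of components of each sort is essential (`exactly`) or inessential
#' (`at_least`, `any`) for membership in the described type.
#'
#' @slot name name of the described type.
#' @slot slots data.frame with columns `type`, `card`
#'   (`"exactly"`, `"at_least"`, `"any"`) and `n` (`NA` for `"any"`).
#' @slot closed logical; if `TRUE`, segments of types not listed are
#'   forbidden.
#' @export
setClass("TypeSpec",
  representation(name = "character", slots = "data.frame", closed = "logical"),
  validity = function(object) {
    sl <- object@slots
    if (!all(c("type", "card", "n") %in% names(sl)))
      return("slots must have columns type, card, n")
    if (!all(sl$card %in% c("exactly", "at_least", "any")))
      return("card must be exactly, at_least or any")
    need <- sl$card %in% c("exactly", "at_least")
    if (any(need & (is.na(sl$n) | sl$n < 1L)))
      return("exactly/at_least slots need n >= 1")
    TRUE
  })

#' Description-logic class expression
#'
#' AST node for the class-expression language: atomic class, boolean
#' connectives, and existential/universal/qualified-cardinality restrictions
#' over a role.
#'
#' @slot op one of `"atom"`, `"not"`, `"and"`, `"or"`, `"some"`, `"only"`,
#'   `"exactly"`, `"min"`, `"max"`.
#' @slot name atomic class name (atoms only).
#' @slot role role name (restrictions only).
#' @slot n cardinality (`exactly`/`min`/`max` only).
#' @slot args list of operand `ClassExpr` objects.
#' @export
setClass("ClassExpr",
  representation(op = "character", name = "character", role = "character",
                 n = "integer", args = "list"),
  validity = function(object) {
    op <- object@op
    if (length(op) != 1L || !op %in%
        c("atom", "not", "and", "or", "some", "only", "exactly", "min", "max"))
      return("unknown operator")
    if (op == "atom" && length(object@name) != 1L)
      return("atomic expression needs a class name")
    if (op %in% c("some", "only", "exactly", "min", "max")) {
      if (length(object@role) != 1L) return("restriction needs a role")
      if (length(object@args) != 1L) return("restriction needs one filler")
    }
    if (op %in% c("exactly", "min") &&
        (length(object@n) != 1L || object@n < 1L))
      return("exactly/min need n >= 1")
    if (op == "max" && (length(object@n) != 1L || object@n < 0L))
      return("max needs n >= 0")
    if (op == "not" && length(object@args) != 1L)
      return("not takes one operand")
    if (op %in% c("and", "or") && length(object@args) < 2L)
      return("and/or take >= 2 operands")
    if (!all(vapply(object@args, is, logical(1), class2 = "ClassExpr")))
      return("operands must be ClassExpr")
    TRUE
  })

#' Terminological axiom
#'
#' Subclass, equivalence or disjointness between two class expressions, with
#' a provenance tag naming the design pattern that generated it and a
#' `regime` marking whether it uses the primitive grain/component relations
#' (`"grain"`) or only proper parthood (`"proper_part"`); `"common"` axioms
#' (hierarchy, disjointness) belong to both regimes.
#'
#' @slot type `"sub"`, `"equiv"` or `"disjoint"`.
#' @slot lhs,rhs the two class expressions.
#' @slot provenance pattern tag, e.g. `"pattern:coll(Propanol_Molecule)"`.
#' @slot regime `"common"`, `"grain"` or `"proper_part"`.
#' @export
setClass("Axiom",
  representation(type = "character", lhs = "ClassExpr", rhs = "ClassExpr",
                 provenance = "character", regime = "character"),
  validity = function(object) {
    if (!object@type %in% c("sub", "equiv", "disjoint"))
      return("axiom type must be sub, equiv or disjoint")
    if (!object@regime %in% c("common", "grain", "proper_part"))
      return("regime must be common, grain or proper_part")
    TRUE
  })

#' Role declarations plus class axioms
#'
#' @slot roles data.frame with columns `name`, `transitive` (logical),
#'   `subroleOf` (character or `NA`), `inverseOf` (character or `NA`).
#' @slot axioms list of [Axiom-class] objects.
#' @export
setClass("TBox",
  representation(roles = "data.frame", axioms = "list"),
  validity = function(object) {
    r <- object@roles
    if (!all(c("name", "transitive", "subroleOf", "inverseOf") %in% names(r)))
      return("roles must have columns name, transitive, subroleOf, inverseOf")
    if (anyDuplicated(r$name)) return("duplicate role names")
    ref <- c(r$subroleOf[!is.na(r$subroleOf)], r$inverseOf[!is.na(r$inverseOf)])
    if (!all(ref %in% r$name))
      return(sprintf("undeclared role '%s' referenced", setdiff(ref, r$name)[1L]))
    if (!all(vapply(object@axioms, is, logical(1), class2 = "Axiom")))
      return("axioms must be Axiom objects")
    used <- unique(unlist(lapply(object@axioms, function(a)
      c(.exprRoles(a@lhs), .exprRoles(a@rhs)))))
    if (!all(used %in% r$name))
      return(sprintf("axiom uses undeclared role '%s'",
                     setdiff(used, r$name)[1L]))
    TRUE
  })

#' Named ontology
#'
#' Named classes, a TBox, and the type registry carrying the atomic-class
#' hierarchy; serializable to OWL 2 via [emitOwl()].
#'
#' @slot name ontology name (used for the IRI).
#' @slot classes declared class names.
#' @slot tbox a [TBox-class].
#' @slot registry a [TypeRegistry-class] for the atomic hierarchy.
#' @export
setClass("Ontology",
  representation(name = "character", classes = "character",
                 tbox = "TBox", registry = "TypeRegistry"))

#' Bounded subsumption verdict
#'
#' @slot holds `TRUE` when no countermodel exists among the enumerated
#'   models (bounded evidence), `FALSE` when a countermodel was found.
#' @slot countermodel a [FiniteModel-class] witnessing the failure, or
#'   `NULL`.
#' @slot counterexample id of the entity in the countermodel that is in the
#'   subclass but not the superclass extension (empty if none).
#' @slot maxSizeChecked largest model size enumerated.
#' @slot modelsChecked number of admissible models evaluated.
#' @slot capped `TRUE` when the resource guard stopped enumeration early,
#'   making the verdict partial.
#' @export
setClass("Verdict",
  representation(holds = "logical", countermodel = "ANY",
                 counterexample = "character", maxSizeChecked = "integer",
                 modelsChecked = "numeric", capped = "logical"),
  validity = function(object) {
    if (identical(object@holds, FALSE) && is.null(object@countermodel))
      return("a failed verdict must carry a countermodel")
    TRUE
  })

#' Relation-property check report
#'
#' @slot property property name checked.
#' @slot modelsChecked number of models evaluated.
#' @slot violations list of violation records (model digest plus witness
#'   tuple); empty iff the property passed.
#' @export
setClass("PropertyReport",
  representation(property = "character", modelsChecked = "integer",
                 violations = "list"))
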