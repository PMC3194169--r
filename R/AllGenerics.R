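#' @describeIn FiniteModel-class number of entities
#' @param x a `FiniteModel`
#' @export
setMethod("length", "FiniteModel", function(x) length(x@entities))

setMethod("show", "FiniteModel", function(object) {
  cat(sprintf("FiniteModel: %d entities, %d direct-part edges\n",
              length(object@entities), nrow(object@directPart)))
  for (e in utils::head(object@entities, 8L)) {
    kids <- object@directPart[object@directPart[, 1L] == e, 2L]
    cat(sprintf("  %s : %s%s\n", e,
                paste(object@instanceOf[[e]], collapse = ", "),
                if (length(kids)) paste0(" -> {", paste(kids, collapse = ", "), "}")
                else ""))
  }
  if (length(object@entities) > 8L)
    cat(sprintf("  ... and %d more\n", length(object@entities) - 8L))
  invisible(object)
})

setMethod("show", "TypeRegistry", function(object) {
  cat(sprintf("TypeRegistry: %d types (%d derived), %d is_a edges, %d disjoint pairs\n",
              nrow(object@typeTable), sum(object@typeTable$kind != "plain"),
              nrow(object@isA), nrow(object@disjoint)))
  invisible(object)
})

setMethod("show", "ClassExpr", function(object) {
  cat(renderClassExpr(object), "\n")
  invisible(object)
})

setMethod("show", "Axiom", function(object) {
  op <- switch(object@type, sub = "SubClassOf", equiv = "EquivalentTo",
               disjoint = "DisjointWith")
  cat(sprintf("%s: %s  %s  [%s; %s]\n", op, renderClassExpr(object@lhs),
              renderClassExpr(object@rhs), object@provenance, object@regime))
  invisible(object)
})

setMethod("show", "TBox", function(object) {
  cat(sprintf("TBox: %d roles, %d axioms\n",
              nrow(object@roles), length(object@axioms)))
  invisible(object)
})

setMethod("show", "Ontology", function(object) {
  cat(sprintf("Ontology '%s': %d classes, %d axioms\n", object@name,
              length(object@classes), length(object@tbox@axioms)))
  invisible(object)
})

setMethod("show", "Verdict", function(object) {
  if (isTRUE(object@holds)) {
    cat(sprintf("Subsumption holds up to size %d (%d models checked%s)\n",
                object@maxSizeChecked, object@modelsChecked,
                if (object@capped) "; enumeration capped, verdict partial" else ""))
  } else {
    cat(sprintf("Subsumption fails: countermodel with %d entities (witness '%s')\n",
                length(object@countermodel@entities), object@counterexample))
  }
  invisible(object)
})

setMethod("show", "PropertyReport", function(object) {
  cat(sprintf("%-16s models=%d  %s\n", object@property, object@modelsChecked,
              if (length(object@violations)) sprintf("VIOLATED (%d witnesses)",
                                                     length(object@violations))
              else "pass"))
  invisible(object)
})

#' Entity ids of a model
#' @param model a [FiniteModel-class]
#' @return character vector of entity ids
#' @export
entities <- function(model) model@entities

#' Axioms of a TBox or Ontology
#' @param x a [TBox-class] or [Ontology-class]
#' @return list of [Axiom-class]
#' @export
axioms <- function(x) if (is(x, "Ontology")) x@tbox@axioms else x@axioms

#' Declared class names of an ontology
#' @param x an [Ontology-class]
#' @return character vector
#' @export
ontologyClasses <- function(x) x@classes
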