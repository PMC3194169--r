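# OWL 2 serialization. Functional-style syntax is the canonical machine
# dialect (and the one the package can read back); Manchester syntax is the
# human-facing one. Output ordering is deterministic: classes alphabetical,
# axioms by provenance tag then by rendered form.

.IRI_BASE <- "http://example.org/mereocoll"

.fq <- function(name) paste0(":", name)

.exprToFunctional <- function(e) {
  switch(e@op,
    atom = .fq(e@name),
    not = sprintf("ObjectComplementOf(%s)",
                  .exprToFunctional(e@args[[1L]])),
    and = sprintf("ObjectIntersectionOf(%s)",
                  paste(vapply(e@args, .exprToFunctional, character(1)),
                        collapse = " ")),
    or = sprintf("ObjectUnionOf(%s)",
                 paste(vapply(e@args, .exprToFunctional, character(1)),
                       collapse = " ")),
    some = sprintf("ObjectSomeValuesFrom(%s %s)", .fq(e@role),
                   .exprToFunctional(e@args[[1L]])),
    only = sprintf("ObjectAllValuesFrom(%s %s)", .fq(e@role),
                   .exprToFunctional(e@args[[1L]])),
    exactly = sprintf("ObjectExactCardinality(%d %s %s)", e@n, .fq(e@role),
                      .exprToFunctional(e@args[[1L]])),
    min = sprintf("ObjectMinCardinality(%d %s %s)", e@n, .fq(e@role),
                  .exprToFunctional(e@args[[1L]])),
    max = sprintf("ObjectMaxCardinality(%d %s %s)", e@n, .fq(e@role),
                  .exprToFunctional(e@args[[1L]])))
}

.axiomToFunctional <- function(a) {
  ann <- sprintf("Annotation(rdfs:comment \"provenance=%s\") Annotation(rdfs:comment \"regime=%s\")",
                 a@provenance, a@regime)
  head <- switch(a@type, sub = "SubClassOf", equiv = "EquivalentClasses",
                 disjoint = "DisjointClasses")
  sprintf("%s(%s %s %s)", head, ann,
          .exprToFunctional(a@lhs), .exprToFunctional(a@rhs))
}

.sortedAxioms <- function(ont) {
  axs <- ont@tbox@axioms
  key <- vapply(axs, function(a) paste(a@provenance, .axiomKey(a)),
                character(1))
  axs[order(key, method = "radix")]
}

.emitFunctional <- function(ont) {
  iri <- sprintf("%s/%s", .IRI_BASE, ont@name)
  roles <- ont@tbox@roles
  lines <- c(
    sprintf("Prefix(:=<%s#>)", iri),
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    sprintf("Ontology(<%s>", iri),
    sprintf("Declaration(Class(%s))",
            .fq(sort(ont@classes, method = "radix"))),
    sprintf("Declaration(ObjectProperty(%s))",
            .fq(sort(roles$name, method = "radix"))))
  for (i in order(roles$name, method = "radix")) {
    if (roles$transitive[i])
      lines <- c(lines, sprintf("TransitiveObjectProperty(%s)",
                                .fq(roles$name[i])))
    if (!is.na(roles$subroleOf[i]))
      lines <- c(lines, sprintf("SubObjectPropertyOf(%s %s)",
                                .fq(roles$name[i]), .fq(roles$subroleOf[i])))
    if (!is.na(roles$inverseOf[i]) && roles$name[i] < roles$inverseOf[i])
      lines <- c(lines, sprintf("InverseObjectProperties(%s %s)",
                                .fq(roles$name[i]), .fq(roles$inverseOf[i])))
  }
  lines <- c(lines,
             vapply(.sortedAxioms(ont), .axiomToFunctional, character(1)),
             ")")
  paste(lines, collapse = "\n")
}

.emitManchester <- function(ont) {
  iri <- sprintf("%s/%s", .IRI_BASE, ont@name)
  roles <- ont@tbox@roles
  out <- c(sprintf("Prefix: : <%s#>", iri),
           sprintf("Ontology: <%s>", iri), "")
  for (i in order(roles$name, method = "radix")) {
    out <- c(out, sprintf("ObjectProperty: %s", roles$name[i]))
    if (roles$transitive[i]) out <- c(out, "    Characteristics: Transitive")
    if (!is.na(roles$subroleOf[i]))
      out <- c(out, sprintf("    SubPropertyOf: %s", roles$subroleOf[i]))
    if (!is.na(roles$inverseOf[i]))
      out <- c(out, sprintf("    InverseOf: %s", roles$inverseOf[i]))
    out <- c(out, "")
  }
  axs <- .sortedAxioms(ont)
  for (cls in sort(ont@classes, method = "radix")) {
    block <- sprintf("Class: %s", cls)
    for (a in axs) {
      if (a@type == "disjoint") next
      if (a@lhs@op == "atom" && a@lhs@name == cls) {
        kw <- if (a@type == "sub") "SubClassOf" else "EquivalentTo"
        block <- c(block,
                   sprintf("    Annotations: rdfs:comment \"provenance=%s\", rdfs:comment \"regime=%s\"",
                           a@provenance, a@regime),
                   sprintf("    %s: %s", kw, renderClassExpr(a@rhs)))
      }
    }
    out <- c(out, block, "")
  }
  for (a in axs)
    if (a@type == "disjoint")
      out <- c(out, sprintf("DisjointClasses: %s, %s",
                            renderClassExpr(a@lhs), renderClassExpr(a@rhs)))
  paste(out, collapse = "\n")
}

#' Serialize an ontology as OWL 2
#'
#' Refuses to emit an ontology whose axioms violate the DL simplicity
#' restriction unless `override = TRUE`, mirroring what an OWL DL editor
#' would accept. Output is deterministic: same ontology, byte-identical
#' document.
#'
#' @param ont an [Ontology-class].
#' @param dialect `"functional"` (canonical, machine-readable back via
#'   [readOwlFunctional()]) or `"manchester"` (human-facing frames).
#' @param file optional path to write to.
#' @param override emit even when [dlSafetyReport()] is non-empty.
#' @return the document as a single character string (invisibly when
#'   written to a file)
#' @export
emitOwl <- function(ont, dialect = c("functional", "manchester"),
                    file = NULL, override = FALSE) {
  dialect <- match.arg(dialect)
  viol <- dlSafetyReport(ont)
  if (length(viol) && !override)
    .stopf("ontology is outside OWL DL (%d violation%s, first: %s); use override = TRUE to emit anyway",
           length(viol), if (length(viol) > 1L) "s" else "", viol[1L])
  doc <- switch(dialect, functional = .emitFunctional(ont),
                manchester = .emitManchester(ont))
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}
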