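# Reader for the functional-style dialect emitted by emitOwl(): enough of
# OWL 2 functional syntax to round-trip the package's own documents.

.ftokenize <- function(text) {
  pat <- paste0("\\(|\\)|\"[^\"]*\"|<[^>]*>|",
                "[A-Za-z]*:[A-Za-z][A-Za-z0-9_'.\\-]*|",
                "[A-Za-z][A-Za-z0-9_]*|[0-9]+|:=")
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(character())
  regmatches(text, list(m))[[1L]]
}

# generic s-expression reader: a term followed by "(" opens a node
.fread <- function(st) {
  t <- st$toks[st$i]; st$i <- st$i + 1L
  if (st$i <= length(st$toks) && identical(st$toks[st$i], "(")) {
    st$i <- st$i + 1L
    args <- list()
    while (!identical(st$toks[st$i], ")")) {
      if (st$i > length(st$toks)) .stopf("unbalanced parentheses in OWL document")
      args <- c(args, list(.fread(st)))
      }
    st$i <- st$i + 1L
    list(head = t, args = args)
  } else {
    t
  }
}

.local <- function(tok) sub("^:", "", tok)

.fToExpr <- function(node) {
  if (is.character(node)) return(atomicClass(.local(node)))
  argE <- function(i) .fToExpr(node$args[[i]])
  switch(node$head,
    ObjectIntersectionOf = do.call(andClass, lapply(node$args, .fToExpr)),
    ObjectUnionOf = do.call(orClass, lapply(node$args, .fToExpr)),
    ObjectComplementOf = notClass(argE(1L)),
    ObjectSomeValuesFrom = someValues(.local(node$args[[1L]]), argE(2L)),
    ObjectAllValuesFrom = onlyValues(.local(node$args[[1L]]), argE(2L)),
    ObjectExactCardinality = exactlyN(.local(node$args[[2L]]),
                                      as.integer(node$args[[1L]]), argE(3L)),
    ObjectMinCardinality = minN(.local(node$args[[2L]]),
                                as.integer(node$args[[1L]]), argE(3L)),
    ObjectMaxCardinality = maxN(.local(node$args[[2L]]),
                                as.integer(node$args[[1L]]), argE(3L)),
    .stopf("unsupported class expression '%s'", node$head))
}

#' Read back a functional-syntax OWL document
#'
#' Parses the subset of OWL 2 functional syntax that [emitOwl()] writes
#' (class and object-property declarations, role characteristics,
#' SubClassOf / EquivalentClasses / DisjointClasses with annotation-borne
#' provenance and regime tags) and rebuilds an [Ontology-class]. The
#' atomic hierarchy of the registry is reconstructed from the
#' atomic-to-atomic subclass and disjointness axioms.
#'
#' @param text the document, or a file path ending in `.ofn`/`.owl`.
#' @return an [Ontology-class]
#' @export
readOwlFunctional <- function(text) {
  if (length(text) == 1L && grepl("\\.(ofn|owl)$", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "\n")
  text <- paste(text, collapse = "\n")
  # strip Prefix declarations; keep the Ontology body
  text <- gsub("Prefix\\([^)]*\\)", "", text)
  st <- new.env(parent = emptyenv())
  st$toks <- .ftokenize(text); st$i <- 1L
  doc <- .fread(st)
  if (!identical(doc$head, "Ontology")) .stopf("not an OWL functional document")
  name <- basename(gsub("[<>]", "", doc$args[[1L]]))
  classes <- character(); roleNames <- character()
  trans <- character(); subOf <- list(); invOf <- list()
  axs <- list(); isA <- list(); disj <- list()
  for (node in doc$args[-1L]) {
    if (is.character(node)) next
    h <- node$head
    if (h == "Declaration") {
      inner <- node$args[[1L]]
      nm <- .local(inner$args[[1L]])
      if (inner$head == "Class") classes <- c(classes, nm)
      else roleNames <- c(roleNames, nm)
    } else if (h == "TransitiveObjectProperty") {
      trans <- c(trans, .local(node$args[[1L]]))
    } else if (h == "SubObjectPropertyOf") {
      subOf[[.local(node$args[[1L]])]] <- .local(node$args[[2L]])
    } else if (h == "InverseObjectProperties") {
      a <- .local(node$args[[1L]]); b <- .local(node$args[[2L]])
      invOf[[a]] <- b; invOf[[b]] <- a
    } else if (h %in% c("SubClassOf", "EquivalentClasses", "DisjointClasses")) {
      prov <- "asserted"; regime <- "common"; operands <- list()
      for (arg in node$args) {
        if (!is.character(arg) && arg$head == "Annotation") {
          val <- gsub("\"", "", arg$args[[2L]])
          if (startsWith(val, "provenance=")) prov <- sub("provenance=", "", val)
          if (startsWith(val, "regime=")) regime <- sub("regime=", "", val)
        } else operands <- c(operands, list(arg))
      }
      lhs <- .fToExpr(operands[[1L]]); rhs <- .fToExpr(operands[[2L]])
      type <- switch(h, SubClassOf = "sub", EquivalentClasses = "equiv",
                     DisjointClasses = "disjoint")
      axs <- c(axs, list(new("Axiom", type = type, lhs = lhs, rhs = rhs,
                             provenance = prov, regime = regime)))
      if (lhs@op == "atom" && rhs@op == "atom") {
        if (type == "sub") isA <- c(isA, list(c(lhs@name, rhs@name)))
        if (type == "disjoint") disj <- c(disj, list(c(lhs@name, rhs@name)))
      }
    }
  }
  reg <- typeRegistry(classes, isA = if (length(isA)) isA else NULL,
                      disjoint = if (length(disj)) disj else NULL)
  roles <- data.frame(
    name = roleNames,
    transitive = roleNames %in% trans,
    subroleOf = vapply(roleNames, function(r)
      if (is.null(subOf[[r]])) NA_character_ else subOf[[r]], character(1)),
    inverseOf = vapply(roleNames, function(r)
      if (is.null(invOf[[r]])) NA_character_ else invOf[[r]], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- ontology(name, reg, axs)
  out@tbox <- new("TBox", roles = roles, axioms = axs)
  out
}
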