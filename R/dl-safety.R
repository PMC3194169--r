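# OWL 2 global restriction on number restrictions: qualified cardinality
# may only be used on simple roles. A role is non-simple when it, its
# inverse, or any (transitive chain of) subrole is transitive. Reasoners
# enforce this to preserve decidability, which is exactly why "exactly 3
# parts" cannot be said through a transitive parthood relation.

# names of all non-simple roles declared in a role table
.nonSimpleRoles <- function(roles) {
  subsOf <- function(r) {
    direct <- roles$name[!is.na(roles$subroleOf) & roles$subroleOf == r]
    out <- direct
    for (d in direct) out <- c(out, subsOf(d))
    unique(out)
  }
  bad <- character()
  for (r in roles$name) {
    related <- unique(c(r, subsOf(r),
                        roles$inverseOf[roles$name == r]))
    related <- related[!is.na(related)]
    if (any(roles$transitive[roles$name %in% related])) bad <- c(bad, r)
  }
  bad
}

#' Check an expression against the OWL DL simplicity restriction
#'
#' Flags every `exactly`/`min`/`max` node whose role is non-simple
#' (transitive, has a transitive subrole, or a transitive inverse). An
#' empty result means the expression is expressible in OWL DL.
#'
#' @param expr a [ClassExpr-class] or Manchester string.
#' @param tb a [TBox-class] declaring the roles (default role box when
#'   omitted).
#' @return character vector of violation messages (empty when safe)
#' @examples
#' isDLSafe(exactlyN("has_proper_part", 3, "Atom"))   # one violation
#' isDLSafe(exactlyN("has_component", 3, "Atom"))     # clean
#' @export
isDLSafe <- function(expr, tb = tbox()) {
  if (is.character(expr)) expr <- parseClassExpr(expr)
  nonSimple <- .nonSimpleRoles(tb@roles)
  walk <- function(e) {
    own <- if (e@op %in% c("exactly", "min", "max") && e@role %in% nonSimple)
      sprintf("number restriction '%s %s %d' uses non-simple role '%s'",
              e@role, e@op, e@n, e@role)
    else character()
    c(own, unlist(lapply(e@args, walk), use.names = FALSE))
  }
  walk(expr)
}

#' DL-safety of a whole ontology or TBox
#'
#' @param x an [Ontology-class] or [TBox-class].
#' @return character vector of violations over all axioms
#' @export
dlSafetyReport <- function(x) {
  tb <- if (is(x, "Ontology")) x@tbox else x
  out <- character()
  for (a in tb@axioms)
    out <- c(out, isDLSafe(a@lhs, tb), isDLSafe(a@rhs, tb))
  out
}
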