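# Constructors for the class-expression AST, plus the Manchester-style
# renderer. The surface syntax is the one ontology editors print:
#   has_grain some H-Atom and has_grain only H-Atom
#   has_proper_part only (Propanol_Molecule or not (Molecule))

.expr <- function(op, name = character(), role = character(),
                  n = integer(), args = list())
  new("ClassExpr", op = op, name = name, role = role, n = n, args = args)

#' Class-expression constructors
#'
#' Build AST nodes of the description-logic class-expression language:
#' atomic classes, boolean connectives, and existential (`some`), universal
#' (`only`) and qualified-cardinality (`exactly`/`min`/`max`) restrictions
#' over a role.
#'
#' @param name atomic class name.
#' @param x operand expression (or, for variadic connectives, several).
#' @param ... operand expressions.
#' @param role role name, e.g. `"has_grain"`.
#' @param n cardinality (`n >= 1` for `exactly`/`min`, `n >= 0` for `max`).
#' @param filler filler class expression or atomic class name (strings are
#'   promoted to atomic classes).
#' @return a [ClassExpr-class]
#' @examples
#' exactlyN("has_grain", 2, "H-Atom")
#' andClass(someValues("has_grain", "H-Atom"), onlyValues("has_grain", "H-Atom"))
#' @export
atomicClass <- function(name) .expr("atom", name = name)

.asExpr <- function(x) if (is.character(x)) atomicClass(x) else x

#' @rdname atomicClass
#' @export
notClass <- function(x) .expr("not", args = list(.asExpr(x)))

#' @rdname atomicClass
#' @export
andClass <- function(...) .expr("and", args = lapply(list(...), .asExpr))

#' @rdname atomicClass
#' @export
orClass <- function(...) .expr("or", args = lapply(list(...), .asExpr))

#' @rdname atomicClass
#' @export
someValues <- function(role, filler)
  .expr("some", role = role, args = list(.asExpr(filler)))

#' @rdname atomicClass
#' @export
onlyValues <- function(role, filler)
  .expr("only", role = role, args = list(.asExpr(filler)))

#' @rdname atomicClass
#' @export
exactlyN <- function(role, n, filler)
  .expr("exactly", role = role, n = as.integer(n), args = list(.asExpr(filler)))

#' @rdname atomicClass
#' @export
minN <- function(role, n, filler)
  .expr("min", role = role, n = as.integer(n), args = list(.asExpr(filler)))

#' @rdname atomicClass
#' @export
maxN <- function(role, n, filler)
  .expr("max", role = role, n = as.integer(n), args = list(.asExpr(filler)))

# all role names occurring in an expression
.exprRoles <- function(e) {
  out <- if (length(e@role)) e@role else character()
  unique(c(out, unlist(lapply(e@args, .exprRoles), use.names = FALSE)))
}

# all atomic class names occurring in an expression
.exprAtoms <- function(e) {
  out <- if (e@op == "atom") e@name else character()
  unique(c(out, unlist(lapply(e@args, .exprAtoms), use.names = FALSE)))
}

#' Render a class expression in Manchester-style syntax
#'
#' Inverse of [parseClassExpr()]: `parseClassExpr(renderClassExpr(e))` is
#' structurally identical to `e`.
#'
#' @param expr a [ClassExpr-class].
#' @return single character string
#' @export
renderClassExpr <- function(expr) .render(expr, parentOp = "")

# Parenthesize according to precedence: not > and > or; restriction
# fillers are primaries (atoms stay bare, anything else gets parentheses).
.render <- function(e, parentOp) {
  wrap <- function(s, needed) if (needed) paste0("(", s, ")") else s
  switch(e@op,
    atom = e@name,
    not = paste0("not ", .renderPrimary(e@args[[1L]])),
    and = wrap(paste(vapply(e@args, .render, character(1), parentOp = "and"),
                     collapse = " and "),
               parentOp %in% c("and", "not", "prim")),
    or = wrap(paste(vapply(e@args, .render, character(1), parentOp = "or"),
                    collapse = " or "),
              parentOp %in% c("or", "and", "not", "prim")),
    some = ,
    only = paste(e@role, e@op, .renderPrimary(e@args[[1L]])),
    exactly = ,
    min = ,
    max = paste(e@role, e@op, e@n, .renderPrimary(e@args[[1L]])))
}

.renderPrimary <- function(e) {
  if (e@op == "atom") e@name
  else if (e@op == "not") paste0("not ", .renderPrimary(e@args[[1L]]))
  else paste0("(", .render(e, parentOp = ""), ")")
}

#' Structural equality of class expressions
#'
#' Operand order inside `and`/`or` is significant (expressions are compared
#' as written, not modulo commutativity).
#' @param a,b [ClassExpr-class] objects.
#' @return logical
#' @export
exprIdentical <- function(a, b) {
  identical(a@op, b@op) && identical(a@name, b@name) &&
    identical(a@role, b@role) && identical(a@n, b@n) &&
    length(a@args) == length(b@args) &&
    all(vapply(seq_along(a@args), function(i)
      exprIdentical(a@args[[i]], b@args[[i]]), logical(1)))
}
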