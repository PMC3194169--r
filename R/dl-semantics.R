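# Finite-model semantics for class expressions. Roles are interpreted over
# the model's direct-parthood graph:
#   has_proper_part  transitive closure of direct parthood
#   proper_part_of   its inverse
#   has_grain        "fol" mode: candidate grains, active only when the
#                    grains are uniform (share a declared type) -- the
#                    executable reading of the first-order definition;
#                    "primitive" mode: the bare direct edges, which is all
#                    a DL reasoner ever sees of an undefined subrole
#   has_component    "fol" mode: proper parthood (unrelativized
#                    componenthood); "primitive" mode: direct edges
# A universal (only) restriction over an entity with no successors is
# vacuously satisfied.

#' Default mereological role box
#'
#' Declares `has_proper_part` (transitive), its inverse `proper_part_of`,
#' and the non-transitive subroles `has_grain` and `has_component`.
#'
#' @return data.frame suitable for the `roles` slot of [TBox-class]
#' @export
defaultRoleBox <- function() {
  data.frame(
    name = c("has_proper_part", "proper_part_of", "has_grain", "has_component"),
    transitive = c(TRUE, TRUE, FALSE, FALSE),
    subroleOf = c(NA, NA, "has_proper_part", "has_proper_part"),
    inverseOf = c("proper_part_of", "has_proper_part", NA, NA),
    stringsAsFactors = FALSE)
}

#' Construct a TBox
#'
#' @param axioms list of [Axiom-class] objects.
#' @param roles role declaration data.frame; defaults to [defaultRoleBox()].
#' @return a [TBox-class]
#' @export
tbox <- function(axioms = list(), roles = defaultRoleBox())
  new("TBox", roles = roles, axioms = axioms)

#' Axiom constructors
#'
#' @param lhs,rhs class expressions or atomic class names.
#' @param provenance pattern tag recording which design pattern generated
#'   the axiom.
#' @param regime `"common"`, `"grain"` or `"proper_part"` (see
#'   [Axiom-class]).
#' @return an [Axiom-class]
#' @export
subClassOf <- function(lhs, rhs, provenance = "asserted", regime = "common")
  new("Axiom", type = "sub", lhs = .asExpr(lhs), rhs = .asExpr(rhs),
      provenance = provenance, regime = regime)

#' @rdname subClassOf
#' @export
equivalentTo <- function(lhs, rhs, provenance = "asserted", regime = "common")
  new("Axiom", type = "equiv", lhs = .asExpr(lhs), rhs = .asExpr(rhs),
      provenance = provenance, regime = regime)

#' @rdname subClassOf
#' @export
disjointWith <- function(lhs, rhs, provenance = "asserted", regime = "common")
  new("Axiom", type = "disjoint", lhs = .asExpr(lhs), rhs = .asExpr(rhs),
      provenance = provenance, regime = regime)

# ---- internal evaluation context --------------------------------------

# ctx fields: n; closures (list of closed type sets per entity, is_a
# applied); kids / desc / parentsDesc (lists of integer vectors); grainCand
# (list of integer vectors); mode.
.makeCtx <- function(model, registry, mode = "fol") {
  ids <- model@entities
  n <- length(ids)
  e <- model@directPart
  edges <- if (nrow(e)) cbind(match(e[, 1L], ids), match(e[, 2L], ids))
           else matrix(integer(), ncol = 2L)
  kids <- .childList(edges, n)
  desc <- .descClosure(kids, n)
  parentsDesc <- vector("list", n)
  for (i in seq_len(n)) parentsDesc[[i]] <- integer(0)
  for (i in seq_len(n)) for (j in desc[[i]])
    parentsDesc[[j]] <- c(parentsDesc[[j]], i)
  up <- .ancestorsOf(registry)
  closures <- lapply(ids, function(x) {
    tp <- model@instanceOf[[x]]
    unknown <- setdiff(tp, names(up))
    if (length(unknown)) .stopf("unknown type '%s'", unknown[1L])
    unique(c(tp, unlist(up[tp], use.names = FALSE)))
  })
  grainCand <- lapply(ids, function(x) {
    g <- if (x %in% names(model@grainDesignation)) model@grainDesignation[[x]]
         else model@directPart[model@directPart[, 1L] == x, 2L]
    match(g, ids)
  })
  list2env(list(ids = ids, n = n, closures = closures, kids = kids,
                desc = desc, parentsDesc = parentsDesc,
                grainCand = grainCand, mode = mode,
                roleCache = list()),
           envir = new.env(parent = emptyenv()))
}

.ctxGrainSucc <- function(ctx) {
  if (ctx$mode == "primitive") return(ctx$kids)
  lapply(seq_len(ctx$n), function(i) {
    g <- ctx$grainCand[[i]]
    if (!length(g)) return(integer(0))
    common <- Reduce(intersect, ctx$closures[g])
    if (length(common)) g else integer(0)
  })
}

.ctxRoleSucc <- function(role, ctx) {
  if (!is.null(ctx$roleCache[[role]])) return(ctx$roleCache[[role]])
  out <- switch(role,
    has_proper_part = ctx$desc,
    proper_part_of = ctx$parentsDesc,
    has_grain = .ctxGrainSucc(ctx),
    has_component = if (ctx$mode == "primitive") ctx$kids else ctx$desc,
    .stopf("role '%s' has no finite-model interpretation", role))
  ctx$roleCache[[role]] <- out
  out
}

# defs: named list class -> list(expr=, axiomIndex=); built from equiv
# axioms with an atomic side (first definition wins, later ones are treated
# as constraints).
.tboxDefs <- function(tb) {
  defs <- list()
  for (k in seq_along(tb@axioms)) {
    a <- tb@axioms[[k]]
    if (a@type != "equiv") next
    lhs <- a@lhs; rhs <- a@rhs
    if (lhs@op != "atom" && rhs@op == "atom") { tmp <- lhs; lhs <- rhs; rhs <- tmp }
    if (lhs@op != "atom") next
    if (!is.null(defs[[lhs@name]])) next
    defs[[lhs@name]] <- list(expr = rhs, axiomIndex = k)
  }
  defs
}

.evalExpr <- function(e, ctx, defs, memo, stack = character()) {
  switch(e@op,
    atom = {
      nm <- e@name
      if (!is.null(defs[[nm]])) {
        if (!is.null(memo[[nm]])) return(memo[[nm]])
        if (nm %in% stack)
          .stopf("cyclic class definition through '%s'", nm)
        v <- .evalExpr(defs[[nm]]$expr, ctx, defs, memo, c(stack, nm))
        memo[[nm]] <- v
        v
      } else {
        vapply(ctx$closures, function(cl) nm %in% cl, logical(1))
      }
    },
    not = !.evalExpr(e@args[[1L]], ctx, defs, memo, stack),
    and = Reduce(`&`, lapply(e@args, .evalExpr, ctx = ctx, defs = defs,
                             memo = memo, stack = stack)),
    or = Reduce(`|`, lapply(e@args, .evalExpr, ctx = ctx, defs = defs,
                            memo = memo, stack = stack)),
    {
      succ <- .ctxRoleSucc(e@role, ctx)
      v <- .evalExpr(e@args[[1L]], ctx, defs, memo, stack)
      counts <- vapply(succ, function(s) sum(v[s]), integer(1))
      switch(e@op,
        some = counts > 0L,
        only = vapply(seq_len(ctx$n), function(i)
          all(v[succ[[i]]]), logical(1)),
        exactly = counts == e@n,
        min = counts >= e@n,
        max = counts <= e@n)
    })
}

# Do the non-definitional axioms of tb hold in ctx?
.tboxHolds <- function(tb, ctx, defs, memo) {
  defIdx <- vapply(defs, function(d) d$axiomIndex, integer(1))
  for (k in seq_along(tb@axioms)) {
    a <- tb@axioms[[k]]
    if (a@type == "equiv" && k %in% defIdx) next
    l <- .evalExpr(a@lhs, ctx, defs, memo)
    r <- .evalExpr(a@rhs, ctx, defs, memo)
    ok <- switch(a@type,
                 sub = !any(l & !r),
                 equiv = identical(l, r),
                 disjoint = !any(l & r))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Extension of a class expression in a finite model
#'
#' Evaluates `expr` under closed-world finite-model semantics: atomic
#' classes by asserted typing closed under `is_a` (or by their defining
#' equivalence when the TBox defines them), boolean connectives classically
#' (`not` is complement within the model's entity set), and role
#' restrictions over the mereological role interpretations described above.
#'
#' @param expr a [ClassExpr-class] (or Manchester string, parsed on the
#'   fly).
#' @param model a [FiniteModel-class].
#' @param registry a [TypeRegistry-class].
#' @param tb a [TBox-class]; its equivalence axioms define named classes.
#' @param mode `"fol"` for the first-order reading of `has_grain`/
#'   `has_component`, `"primitive"` to interpret both as bare direct edges
#'   (what a DL reasoner sees of an undefined subrole).
#' @return character vector of entity ids satisfying `expr`
#' @examples
#' m <- makeMolecule("H2O")
#' classExtension(exactlyN("has_component", 2, "H-Atom"), m$model, m$registry)
#' @export
classExtension <- function(expr, model, registry, tb = tbox(), mode = "fol") {
  if (is.character(expr)) expr <- parseClassExpr(expr)
  known <- c(registry@typeTable$name, names(.tboxDefs(tb)),
             unlist(lapply(tb@axioms, function(a)
               c(.exprAtoms(a@lhs), .exprAtoms(a@rhs)))))
  unknown <- setdiff(.exprAtoms(expr), known)
  if (length(unknown)) .stopf("undeclared class '%s'", unknown[1L])
  unknownRole <- setdiff(.exprRoles(expr), tb@roles$name)
  if (length(unknownRole)) .stopf("undeclared role '%s'", unknownRole[1L])
  ctx <- .makeCtx(model, registry, mode)
  defs <- .tboxDefs(tb)
  memo <- new.env(parent = emptyenv())
  model@entities[.evalExpr(expr, ctx, defs, memo)]
}
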