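#' Build a type registry
#'
#' @param types character vector of plain type names to declare.
#' @param isA two-column character matrix or a list of `c(child, parent)`
#'   pairs; parents are declared implicitly.
#' @param disjoint two-column character matrix or list of pairs declared
#'   mutually disjoint.
#' @return a [TypeRegistry-class]
#' @examples
#' reg <- typeRegistry(c("Atom", "H-Atom"), isA = list(c("H-Atom", "Atom")))
#' isSubtypeOf(reg, "H-Atom", "Atom")
#' @export
typeRegistry <- function(types = character(), isA = NULL, disjoint = NULL) {
  isA <- .pairMatrix(isA)
  disjoint <- .pairMatrix(disjoint)
  all <- unique(c(types, as.character(isA), as.character(disjoint)))
  tt <- data.frame(name = all, kind = rep("plain", length(all)),
                   base = rep(NA_character_, length(all)),
                   n = rep(NA_integer_, length(all)),
                   stringsAsFactors = FALSE)
  new("TypeRegistry", typeTable = tt, isA = isA, disjoint = disjoint)
}

.pairMatrix <- function(x) {
  if (is.null(x)) return(matrix(character(), ncol = 2L))
  if (is.list(x)) x <- do.call(rbind, x)
  mode(x) <- "character"
  if (!length(x)) return(matrix(character(), ncol = 2L))
  matrix(x, ncol = 2L)
}

#' Name of the derived collective type of a base type
#'
#' The `_COLL` suffix is a naming convention: `collName("Cow")` is the type
#' of collectives all of whose grains are cows.
#' @param base base type name.
#' @return character name
#' @export
collName <- function(base) paste0(base, "_COLL")

#' Name of the derived n-collective type of a base type
#'
#' Strict collectives with a fixed grain count; pairs (`n = 2`) follow the
#' established `_PAIR` convention, other counts get an explicit `_3_COLL`,
#' `_4_COLL`, ... suffix.
#' @param base base type name.
#' @param n grain count (>= 1).
#' @return character name
#' @export
nCollName <- function(base, n) {
  if (n == 2L) paste0(base, "_PAIR") else paste0(base, "_", n, "_COLL")
}

#' Register a derived collective type
#'
#' Declares `collName(base)` in the registry. By design the collective type
#' is left unrelated to its base in the hierarchy (whether `Entity_COLL`
#' is itself an `Entity` is an open modelling question this package does not
#' prejudge).
#' @param registry a [TypeRegistry-class].
#' @param base declared base type.
#' @param n for `registerNColl`, the fixed grain count.
#' @return the extended registry
#' @export
registerColl <- function(registry, base) {
  .addDerived(registry, base, collName(base), "coll", NA_integer_)
}

#' @rdname registerColl
#' @export
registerNColl <- function(registry, base, n) {
  n <- as.integer(n)
  if (n < 1L) .stopf("an n-collective needs n >= 1, got %d", n)
  .addDerived(registry, base, nCollName(base, n), "ncoll", n)
}

.addDerived <- function(registry, base, name, kind, n) {
  tt <- registry@typeTable
  if (!base %in% tt$name) .stopf("unknown base type '%s'", base)
  if (name %in% tt$name) return(registry)  # idempotent
  tt <- rbind(tt, data.frame(name = name, kind = kind, base = base, n = n,
                             stringsAsFactors = FALSE))
  initialize(registry, typeTable = tt)
}

#' Declare additional plain types or hierarchy edges
#' @inheritParams registerColl
#' @param types plain type names to add.
#' @param isA additional (child, parent) pairs.
#' @param disjoint additional disjoint pairs.
#' @return the extended registry
#' @export
extendRegistry <- function(registry, types = character(), isA = NULL,
                           disjoint = NULL) {
  isA <- rbind(registry@isA, .pairMatrix(isA))
  disjoint <- rbind(registry@disjoint, .pairMatrix(disjoint))
  tt <- registry@typeTable
  newNames <- setdiff(unique(c(types, as.character(isA), as.character(disjoint))),
                      tt$name)
  if (length(newNames))
    tt <- rbind(tt, data.frame(name = newNames, kind = "plain",
                               base = NA_character_, n = NA_integer_,
                               stringsAsFactors = FALSE))
  new("TypeRegistry", typeTable = tt, isA = isA, disjoint = disjoint)
}

# named list: type -> strict ancestors under is_a
.ancestorsOf <- function(registry) {
  ids <- registry@typeTable$name
  n <- length(ids)
  if (!n) return(list())
  e <- registry@isA
  edges <- if (nrow(e)) cbind(match(e[, 1L], ids), match(e[, 2L], ids))
           else matrix(integer(), ncol = 2L)
  up <- .descClosure(.childList(edges, n), n)
  stats::setNames(lapply(up, function(i) ids[i]), ids)
}

#' Reflexive-transitive closure of asserted types under is_a
#'
#' @param registry a [TypeRegistry-class].
#' @param types character vector of type names.
#' @return character vector: `types` plus all their ancestors
#' @export
typeClosure <- function(registry, types) {
  unknown <- setdiff(types, registry@typeTable$name)
  if (length(unknown)) .stopf("unknown type '%s'", unknown[1L])
  up <- .ancestorsOf(registry)
  unique(c(types, unlist(up[types], use.names = FALSE)))
}

#' Is one type subsumed by another?
#'
#' @inheritParams typeClosure
#' @param a,b declared type names.
#' @return `TRUE` iff `a` is `b` or a (transitive) `is_a` descendant of `b`
#' @export
isSubtypeOf <- function(registry, a, b) b %in% typeClosure(registry, a)

#' Are two type sets compatible with declared disjointness?
#'
#' Used when admitting enumerated models: an entity may not instantiate two
#' types whose closures contain a declared disjoint pair.
#' @inheritParams typeClosure
#' @return `TRUE` when no disjoint pair is jointly instantiated
#' @export
typesCompatible <- function(registry, types) {
  if (!nrow(registry@disjoint)) return(TRUE)
  clo <- typeClosure(registry, types)
  for (k in seq_len(nrow(registry@disjoint)))
    if (all(registry@disjoint[k, ] %in% clo)) return(FALSE)
  TRUE
}
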