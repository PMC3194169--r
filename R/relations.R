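# has_grain, has_component and the collective axioms, evaluated against a
# finite model. Grain-Existence: a collective must have at least one grain
# (singletons allowed, empty collectives rejected). Mono-Sortality: every
# grain must instantiate the base type.

#' Is an entity a collective of a given base type?
#'
#' `TRUE` iff `x` has at least one candidate grain and every grain
#' instantiates `base` under the `is_a` closure. An entity with no grains is
#' never a collective of anything (allowing empty collectives would make any
#' grainless entity an instance of every collective type).
#'
#' @param model a [FiniteModel-class].
#' @param registry a [TypeRegistry-class] declaring `base`.
#' @param x entity id.
#' @param base type name of the would-be grains.
#' @return logical
#' @examples
#' reg <- typeRegistry(c("Fruit", "Apple", "Pear"),
#'                     isA = list(c("Apple", "Fruit"), c("Pear", "Fruit")))
#' m <- buildModel(list(basket = "Basket", a = "Apple", p = "Pear"),
#'                 list(c("basket", "a"), c("basket", "p")))
#' satisfiesColl(m, reg, "basket", "Fruit")  # TRUE
#' satisfiesColl(m, reg, "basket", "Apple")  # FALSE
#' @export
satisfiesColl <- function(model, registry, x, base) {
  .checkEntity(model, x)
  if (!base %in% registry@typeTable$name) .stopf("unknown type '%s'", base)
  g <- grainsOf(model, x)
  if (!length(g)) return(FALSE)
  all(vapply(g, function(y)
    base %in% typeClosure(registry, model@instanceOf[[y]]), logical(1)))
}

# types shared by every grain of x (closed under is_a); character(0) when
# x has no grains or they have no common sort
.commonGrainTypes <- function(model, registry, x) {
  g <- grainsOf(model, x)
  if (!length(g)) return(character())
  Reduce(intersect, lapply(g, function(y)
    typeClosure(registry, model@instanceOf[[y]])))
}

#' The has_grain relation
#'
#' `x has_grain y` holds iff `y` is a candidate grain of `x` (hence a proper
#' part) and the grains of `x` are uniform: some declared type is
#' instantiated by every grain of `x`. Uniformity makes the relation
#' irreflexive, asymmetric and non-transitive (a galaxy collects stars and a
#' star collects molecules, yet a galaxy does not collect molecules).
#'
#' @inheritParams satisfiesColl
#' @param y entity id of the candidate grain.
#' @return logical
#' @export
hasGrain <- function(model, registry, x, y) {
  .checkEntity(model, x); .checkEntity(model, y)
  if (!y %in% grainsOf(model, x)) return(FALSE)
  length(.commonGrainTypes(model, registry, x)) > 0L
}

#' Is an entity a strict n-collective?
#'
#' `TRUE` iff `x` is a collective of `base` with exactly `n` grains. Pairs
#' are the case `n = 2`; `n = 1` is the (allowed) singleton collective.
#'
#' @inheritParams satisfiesColl
#' @param n required grain count, `n >= 1`.
#' @return logical
#' @export
isNColl <- function(model, registry, x, base, n) {
  if (n < 1L) .stopf("an n-collective needs n >= 1, got %d", n)
  satisfiesColl(model, registry, x, base) &&
    length(grainsOf(model, x)) == n
}

#' Construct a candidate partition
#'
#' @param whole entity id of the compound.
#' @param segments entity ids of the segments (order irrelevant).
#' @return a [Partition-class]
#' @export
partition <- function(whole, segments)
  new("Partition", whole = whole, segments = as.character(segments))

#' Is a partition valid against a model?
#'
#' Checks the defining conditions of a partition, read over finite
#' discrete models where two entities overlap iff their
#' part-closures-including-self intersect: (a) each segment is a proper
#' part of the whole, (b) no two segments overlap, and (c) the segments
#' jointly exhaust the whole -- every proper part of the whole overlaps
#' some segment. The overlap reading of exhaustion lets a partition
#' crisscross granularity levels (half a chain into monomers, the rest
#' into atoms): the monomer that was skipped over still overlaps its
#' atoms' segments.
#'
#' @param model a [FiniteModel-class].
#' @param p a [Partition-class].
#' @return logical
#' @export
isValidPartition <- function(model, p) {
  .checkEntity(model, p@whole)
  for (s in p@segments) .checkEntity(model, s)
  if (anyDuplicated(p@segments)) return(FALSE)
  clos <- .partsClosure(model)
  whole <- clos[[p@whole]]
  if (!all(p@segments %in% whole)) return(FALSE)
  segClos <- lapply(p@segments, function(s) c(s, clos[[s]]))
  pooled <- unlist(segClos, use.names = FALSE)
  if (anyDuplicated(pooled)) return(FALSE)      # pairwise overlap
  all(vapply(whole, function(q)                 # joint exhaustion
    q %in% pooled || any(clos[[q]] %in% pooled), logical(1)))
}

#' The has_component relation
#'
#' Relativized to a partition, `x has_component y` holds iff `y` is a
#' segment of a valid partition of `x` (a part of a segment is not itself a
#' component with respect to that partition). Unrelativized, componenthood
#' reduces to proper parthood: in a discrete finite model every proper part
#' extends to some partition by taking the remaining atoms as singleton
#' segments.
#'
#' @inheritParams isValidPartition
#' @param x,y entity ids.
#' @param p optional [Partition-class]; must be valid when supplied.
#' @return logical
#' @export
hasComponent <- function(model, x, y, p = NULL) {
  .checkEntity(model, x); .checkEntity(model, y)
  if (!is.null(p)) {
    if (!identical(p@whole, x)) .stopf("partition is of '%s', not '%s'",
                                       p@whole, x)
    if (!isValidPartition(model, p)) .stopf(
      "invalid partition of '%s': segments must be disjoint proper parts that jointly exhaust the whole",
      x)
    return(y %in% p@segments)
  }
  y %in% properParts(model, x)
}

#' Proper parts of an entity at a granularity level
#'
#' The components of `x` on a level indicated by one type (e.g. `Molecule`,
#' `Atom`) or a disjunction of types (e.g. `Proton`, `Neutron`, `Electron`).
#'
#' @inheritParams satisfiesColl
#' @param level character vector of one or more declared level types.
#' @return character vector of entity ids
#' @export
componentsAtLevel <- function(model, registry, x, level) {
  unknown <- setdiff(level, registry@typeTable$name)
  if (length(unknown)) .stopf("unknown type '%s'", unknown[1L])
  pp <- properParts(model, x)
  pp[vapply(pp, function(y)
    any(level %in% typeClosure(registry, model@instanceOf[[y]])), logical(1))]
}

#' Construct a composition specification
#'
#' @param name name of the described type.
#' @param slots list of slot descriptions: `exactly(type, n)`,
#'   `atLeast(type, n)` or `anyNumber(type)`.
#' @param closed forbid segments of unlisted types?
#' @return a [TypeSpec-class]
#' @examples
#' water <- typeSpec("Water_Molecule",
#'                   list(exactly("O-Atom", 1), exactly("H-Atom", 2)),
#'                   closed = TRUE)
#' @export
typeSpec <- function(name, slots, closed = TRUE) {
  sl <- do.call(rbind, lapply(slots, as.data.frame))
  new("TypeSpec", name = name, slots = sl, closed = closed)
}

#' @rdname typeSpec
#' @param type component type of the slot.
#' @param n slot cardinality.
#' @export
exactly <- function(type, n)
  list(type = type, card = "exactly", n = as.integer(n))

#' @rdname typeSpec
#' @export
atLeast <- function(type, n)
  list(type = type, card = "at_least", n = as.integer(n))

#' @rdname typeSpec
#' @export
anyNumber <- function(type)
  list(type = type, card = "any", n = NA_integer_)

# Does a multiset of segment type-closures satisfy a spec? `closures` is a
# list of character vectors (one per segment).
.specSatisfied <- function(spec, closures) {
  sl <- spec@slots
  matched <- rep(FALSE, length(closures))
  for (i in seq_len(nrow(sl))) {
    hit <- vapply(closures, function(cl) sl$type[i] %in% cl, logical(1))
    matched <- matched | hit
    cnt <- sum(hit)
    ok <- switch(sl$card[i],
                 exactly  = cnt == sl$n[i],
                 at_least = cnt >= sl$n[i],
                 any      = TRUE)
    if (!ok) return(FALSE)
  }
  !(spec@closed && any(!matched))
}

#' Is a partitioned entity a strict compound under a specification?
#'
#' A strict compound is one from which no segment can be removed and to
#' which no further segment (of any slot type) can be added while the
#' result still satisfies the specification. Decided by re-checking the
#' cardinality spec under every single-segment removal and every
#' single-segment hypothetical addition. A portion of water (spec: at least
#' one water molecule) is not strict, since removing a molecule leaves a
#' portion of water behind.
#'
#' @inheritParams satisfiesColl
#' @param p a valid [Partition-class] of `x`.
#' @param spec a [TypeSpec-class].
#' @return logical
#' @export
isStrictCompound <- function(model, registry, x, p, spec) {
  if (!identical(p@whole, x)) .stopf("partition is of '%s', not '%s'", p@whole, x)
  if (!isValidPartition(model, p)) .stopf(
    "invalid partition of '%s'", x)
  closures <- lapply(p@segments, function(s)
    typeClosure(registry, model@instanceOf[[s]]))
  if (!.specSatisfied(spec, closures)) return(FALSE)
  for (i in seq_along(closures))
    if (.specSatisfied(spec, closures[-i])) return(FALSE)
  for (tp in unique(spec@slots$type))
    if (.specSatisfied(spec, c(closures, list(typeClosure(registry, tp)))))
      return(FALSE)
  TRUE
}
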