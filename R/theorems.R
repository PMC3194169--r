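# Executable verification of the relation-algebra properties of has_grain.
# The four universal properties (irreflexivity, asymmetry, propagation
# through parthood in both directions) are theorems of the definitions, so
# any violation on any buildable model is a bug; non-transitivity is
# witnessed, not universal.

#' Check the universal properties of has_grain over a model suite
#'
#' Exhaustively evaluates, on every model, all entity tuples for:
#' \describe{
#'   \item{irreflexivity}{never `x has_grain x`.}
#'   \item{asymmetry}{`x has_grain y` excludes `y has_grain x`.}
#'   \item{propagation_I}{`x has_part y` and `y has_grain z` imply that
#'     `z` is a proper part of `x`.}
#'   \item{propagation_II}{`x has_grain y` and `y has_part z` imply that
#'     `z` is a proper part of `x`.}
#' }
#' `has_part` is read inclusively (`y` a proper part of `x`, or `y = x`).
#'
#' @param models list of [FiniteModel-class] objects.
#' @param registry a [TypeRegistry-class] covering the models' types.
#' @return named list of four [PropertyReport-class] objects
#' @export
checkRelationProperties <- function(models, registry) {
  props <- c("irreflexivity", "asymmetry", "propagation_I", "propagation_II")
  viol <- stats::setNames(vector("list", length(props)), props)
  for (p in props) viol[[p]] <- list()
  note <- function(p, model, witness)
    viol[[p]][[length(viol[[p]]) + 1L]] <<-
      list(model = modelDigest(model), witness = witness)
  for (model in models) {
    ctx <- .makeCtx(model, registry, mode = "fol")
    gs <- .ctxGrainSucc(ctx)
    desc <- ctx$desc
    ids <- ctx$ids
    n <- ctx$n
    for (x in seq_len(n)) {
      if (x %in% gs[[x]]) note("irreflexivity", model, ids[x])
      for (y in gs[[x]]) {
        if (x %in% gs[[y]])
          note("asymmetry", model, c(ids[x], ids[y]))
        # propagation II: parts of a grain are parts of the collective
        for (z in desc[[y]])
          if (!z %in% desc[[x]])
            note("propagation_II", model, c(ids[x], ids[y], ids[z]))
      }
      # propagation I: grains of a part are parts of the whole
      for (y in c(x, desc[[x]]))
        for (z in gs[[y]])
          if (!z %in% desc[[x]])
            note("propagation_I", model, c(ids[x], ids[y], ids[z]))
    }
  }
  lapply(stats::setNames(props, props), function(p)
    new("PropertyReport", property = p,
        modelsChecked = length(models), violations = viol[[p]]))
}

#' Search a model for a non-transitivity witness
#'
#' Finds entities `x, y, z` with `x has_grain y` and `y has_grain z` but
#' not `x has_grain z` -- e.g. a galaxy collects stars and a star collects
#' molecules, yet the galaxy does not collect molecules.
#'
#' @inheritParams checkRelationProperties
#' @param model a [FiniteModel-class].
#' @return character vector `c(x, y, z)` or `NULL` when no witness exists
#' @export
findNonTransitivityWitness <- function(model, registry) {
  ctx <- .makeCtx(model, registry, mode = "fol")
  gs <- .ctxGrainSucc(ctx)
  for (x in seq_len(ctx$n))
    for (y in gs[[x]])
      for (z in gs[[y]])
        if (!z %in% gs[[x]])
          return(ctx$ids[c(x, y, z)])
  NULL
}

#' Run the seeded random-model property suite
#'
#' Generates `nModels` random models of at most `maxEntities` entities over
#' a small stratified vocabulary and checks the four universal properties
#' on all of them.
#'
#' @param nModels number of random models (default 500).
#' @param maxEntities maximum entities per model (default 8).
#' @param seed integer seed; the suite is fully reproducible.
#' @return list with `reports` (see [checkRelationProperties()]),
#'   `registry`, and `pass` (logical: no violations anywhere)
#' @export
runPropertySuite <- function(nModels = 500L, maxEntities = 8L, seed = 0L) {
  reg <- typeRegistry(
    c("Thing"),
    isA = list(c("A", "Thing"), c("B", "Thing"), c("C", "Thing"),
               c("A1", "A"), c("A2", "A"), c("B1", "B")))
  vocab <- c("A", "A1", "A2", "B", "B1", "C", "Thing")
  sizes <- ((seq_len(nModels) + seed) %% maxEntities) + 1L
  models <- lapply(seq_len(nModels), function(i)
    randomModel(sizes[i], vocab, seed = seed + i))
  reports <- checkRelationProperties(models, reg)
  list(reports = reports, registry = reg,
       pass = all(vapply(reports, function(r)
         length(r@violations) == 0L, logical(1))))
}

#' Serialize property reports to JSON
#'
#' @param reports list of [PropertyReport-class].
#' @param path optional output path.
#' @return the JSON string, invisibly when written
#' @export
propertyReportJson <- function(reports, path = NULL) {
  obj <- lapply(reports, function(r)
    list(property = r@property, models_checked = r@modelsChecked,
         violations = r@violations, pass = length(r@violations) == 0L))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
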