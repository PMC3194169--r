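#' Build and validate a finite mereological model
#'
#' Entities are declared through `typeAssignments`; `partEdges` records
#' direct parthood (whole, part). The parthood graph must be acyclic, since
#' proper parthood is irreflexive; a cycle is rejected naming an offending
#' entity.
#'
#' @param typeAssignments named list mapping each entity id to a non-empty
#'   character vector of type names.
#' @param partEdges list of `c(whole, part)` pairs or a two-column character
#'   matrix; may be empty.
#' @param grainDesignation optional named list mapping an entity to the
#'   subset of its direct parts designated as grains.
#' @return a validated [FiniteModel-class]
#' @examples
#' m <- buildModel(
#'   list(water1 = "Water_Molecule", o1 = "O-Atom", h1 = "H-Atom", h2 = "H-Atom"),
#'   list(c("water1", "o1"), c("water1", "h1"), c("water1", "h2")))
#' properParts(m, "water1")
#' @export
buildModel <- function(typeAssignments = list(), partEdges = NULL,
                       grainDesignation = NULL) {
  edges <- .pairMatrix(partEdges)
  ids <- names(typeAssignments)
  unknown <- setdiff(as.character(edges), ids)
  if (length(unknown)) .stopf("unknown entity '%s' in part edges", unknown[1L])
  new("FiniteModel",
      entities = as.character(ids),
      instanceOf = lapply(typeAssignments, as.character),
      directPart = edges,
      grainDesignation = if (is.null(grainDesignation)) list()
                         else lapply(grainDesignation, as.character))
}

.checkEntity <- function(model, x) {
  if (!x %in% model@entities) .stopf("unknown entity '%s'", x)
}

.directPartsOf <- function(model, x)
  model@directPart[model@directPart[, 1L] == x, 2L]

# full descendant closure for every entity, as a named list
.partsClosure <- function(model) {
  ids <- model@entities
  n <- length(ids)
  e <- model@directPart
  edges <- if (nrow(e)) cbind(match(e[, 1L], ids), match(e[, 2L], ids))
           else matrix(integer(), ncol = 2L)
  desc <- .descClosure(.childList(edges, n), n)
  stats::setNames(lapply(desc, function(i) ids[i]), ids)
}

#' Proper parts of an entity
#'
#' Transitive closure of direct parthood; interprets `has_proper_part`.
#' Never contains `x` itself (acyclicity is enforced at build time).
#'
#' @param model a [FiniteModel-class].
#' @param x entity id.
#' @return character vector of entity ids
#' @export
properParts <- function(model, x) {
  .checkEntity(model, x)
  .partsClosure(model)[[x]]
}

#' Candidate grains of an entity
#'
#' Returns the explicitly designated grains when a designation is recorded,
#' otherwise the direct proper parts. The direct-part default encodes the
#' reading that a water portion's grains are its molecules, never the atoms
#' further down.
#'
#' @inheritParams properParts
#' @return character vector of entity ids (possibly empty)
#' @export
grainsOf <- function(model, x) {
  .checkEntity(model, x)
  if (x %in% names(model@grainDesignation)) model@grainDesignation[[x]]
  else unname(.directPartsOf(model, x))
}

#' Serialize a model to YAML or JSON
#'
#' Document layout: `entities` (id to list of types), `parts` (list of
#' `[whole, part]` pairs), `grains` (id to list of designated grain ids).
#'
#' @param model a [FiniteModel-class].
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly
#' @export
writeModel <- function(model, path) {
  doc <- list(
    entities = model@instanceOf,
    parts = if (nrow(model@directPart))
      lapply(seq_len(nrow(model@directPart)),
             function(i) as.character(model@directPart[i, ])) else list(),
    grains = model@grainDesignation)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname writeModel
#' @return for `readModel`, the parsed, validated [FiniteModel-class]
#' @export
readModel <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyMatrix = FALSE)
  grains <- doc$grains
  if (is.null(grains) || length(grains) == 0L) grains <- NULL
  buildModel(lapply(doc$entities, as.character),
             lapply(doc$parts, as.character),
             if (is.null(grains)) NULL else lapply(grains, as.character))
}

#' Stable digest of a model
#'
#' A short deterministic fingerprint used in property-violation reports.
#' @param model a [FiniteModel-class].
#' @return single character string
#' @export
modelDigest <- function(model) {
  parts <- apply(model@directPart, 1L, paste, collapse = ">")
  lab <- vapply(model@entities, function(e)
    paste0(e, ":", paste(sort(model@instanceOf[[e]]), collapse = "+")),
    character(1))
  txt <- paste(c(sort(lab), sort(parts)), collapse = ";")
  # tiny FNV-style rolling hash; stability matters, cryptography does not
  h <- 2166136261 %% 268435456
  for (cp in utf8ToInt(txt))
    h <- (bitwXor(as.integer(h), cp) * 16777619) %% 268435456
  sprintf("m%07x-%d", as.integer(h), length(model@entities))
}
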