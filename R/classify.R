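# The four-way classifier: mono-/multi-sortality at a granularity level
# crossed with strict/flexible cardinality gives flexible collectives
# (a portion of water), strict collectives (a pair of kidneys), flexible
# compounds (a hand) and strict compounds (a propanol molecule).

# Minimal asserted types of one entity below the level type(s): asserted
# types subsumed by a level type, with types dropped when a more specific
# asserted type sits below them.
.minimalLevelTypes <- function(model, registry, y, level) {
  up <- .ancestorsOf(registry)
  cand <- Filter(function(t) any(level %in% c(t, up[[t]])),
                 model@instanceOf[[y]])
  keep <- vapply(cand, function(t)
    !any(vapply(cand, function(s) s != t && t %in% up[[s]], logical(1))),
    logical(1))
  sort(unique(cand[keep]))
}

#' Is an entity mono-sortal at a granularity level?
#'
#' Mono-sortality is judged on the minimal asserted types of the parts at
#' the level, not on a shared supertype (under a shared supertype every
#' complex is trivially mono-sortal at its own level). It is therefore both
#' granularity dependent and specificity dependent: a portion of water is
#' mono-sortal at the molecule level but multi-sortal at the atom level,
#' while an O2/O3 mixture is multi-sortal at the molecule level but
#' mono-sortal at the atom level; a basket of fruits described as apples
#' and pears is multi-sortal.
#'
#' @inheritParams componentsAtLevel
#' @return logical
#' @export
isMonoSortal <- function(model, registry, x, level) {
  parts <- componentsAtLevel(model, registry, x, level)
  if (!length(parts)) .stopf("'%s' has no parts at level {%s}", x,
                             paste(level, collapse = ", "))
  sorts <- lapply(parts, .minimalLevelTypes,
                  model = model, registry = registry, level = level)
  if (any(lengths(sorts) == 0L)) return(FALSE)
  all(vapply(sorts, identical, logical(1), y = sorts[[1L]]))
}

#' Classify a complex entity into one of the four categories
#'
#' Crosses mono-/multi-sortality of the parts at `level` with the
#' strictness of the composition specification (`exactly` slots make the
#' component count essential):
#' mono-sortal and flexible = `"flexible_collective"`; mono-sortal with an
#' exact cardinality = `"strict_collective"`; multi-sortal and flexible =
#' `"flexible_compound"`; multi-sortal with an exact cardinality =
#' `"strict_compound"`. Total over entities with at least one part at the
#' level.
#'
#' @inheritParams componentsAtLevel
#' @param spec a [TypeSpec-class] describing the composition of `x`'s type.
#' @return one of the four category strings
#' @export
classifyComplex <- function(model, registry, x, spec, level) {
  mono <- isMonoSortal(model, registry, x, level)
  strict <- any(spec@slots$card == "exactly")
  if (mono) {
    if (strict) "strict_collective" else "flexible_collective"
  } else {
    if (strict) "strict_compound" else "flexible_compound"
  }
}
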