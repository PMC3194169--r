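# Bounded-model subsumption oracle. True entailment over the first-order
# reading of the mereological roles is not decidable in general, so the
# oracle enumerates all acyclic finite models up to a size bound over a
# given atomic vocabulary and reports either a concrete countermodel or
# "holds up to size k" (bounded evidence, not a proof).
#
# Enumeration: models of increasing size; for each size, every DAG with
# edges directed from lower to higher entity index (every DAG admits a
# topological order, so this covers all shapes up to relabelling), edge
# sets in order of increasing edge count; every labelling of entities with
# single atomic types from the vocabulary, closed under is_a. Deterministic
# throughout, no randomness.

.bitCount <- function(x) {
  n <- 0L
  while (x > 0) { n <- n + (x %% 2); x <- x %/% 2 }
  n
}

# drop axioms the single-label + is_a-closure enumeration satisfies by
# construction, so the per-model admissibility check stays cheap
.pruneAxioms <- function(tb, registry) {
  keep <- vapply(tb@axioms, function(a) {
    if (a@type == "sub" && a@lhs@op == "atom" && a@rhs@op == "atom" &&
        a@lhs@name %in% registry@typeTable$name &&
        isSubtypeOf(registry, a@lhs@name, a@rhs@name)) return(FALSE)
    if (a@type == "disjoint" && a@lhs@op == "atom" && a@rhs@op == "atom") {
      dj <- registry@disjoint
      for (k in seq_len(nrow(dj)))
        if (setequal(dj[k, ], c(a@lhs@name, a@rhs@name))) return(FALSE)
    }
    TRUE
  }, logical(1))
  initialize(tb, axioms = tb@axioms[keep])
}

# Visits every admissible (tbox-satisfying) model; `test` returns NULL to
# continue or any non-NULL result to stop the search.
.searchModels <- function(tb, registry, vocab, maxSize, mode, maxModels, test) {
  unknown <- setdiff(vocab, registry@typeTable$name)
  if (length(unknown)) .stopf("vocabulary type '%s' not declared", unknown[1L])
  labelClo <- lapply(vocab, function(v) typeClosure(registry, v))
  tbP <- .pruneAxioms(tb, registry)
  defs <- .tboxDefs(tbP)
  nlab <- length(vocab)
  iter <- 0; checked <- 0
  for (n in seq_len(maxSize)) {
    ut <- upper.tri(diag(n))
    pairIdx <- which(ut, arr.ind = TRUE)   # (whole, part), whole < part
    npairs <- nrow(pairIdx)
    masks <- seq.int(0L, 2^npairs - 1L)
    masks <- masks[order(vapply(masks, .bitCount, numeric(1)), masks)]
    labGrid <- as.matrix(expand.grid(rep(list(seq_len(nlab)), n)))
    bits <- 2^(seq_len(npairs) - 1L)
    for (mask in masks) {
      edges <- pairIdx[bitwAnd(mask, bits) > 0, , drop = FALSE]
      storage.mode(edges) <- "integer"
      kids <- .childList(edges, n)
      desc <- .descClosure(kids, n)
      parentsDesc <- vector("list", n)
      for (i in seq_len(n)) parentsDesc[[i]] <- integer(0)
      for (i in seq_len(n)) for (j in desc[[i]])
        parentsDesc[[j]] <- c(parentsDesc[[j]], i)
      baseCache <- list(has_proper_part = desc, proper_part_of = parentsDesc)
      if (mode == "primitive") {
        baseCache$has_grain <- kids
        baseCache$has_component <- kids
      } else {
        baseCache$has_component <- desc
      }
      for (li in seq_len(nrow(labGrid))) {
        iter <- iter + 1
        if (iter > maxModels)
          return(list(result = NULL, checked = checked, capped = TRUE,
                      size = n))
        labels <- labGrid[li, ]
        ctx <- list2env(list(
          ids = paste0("e", seq_len(n)), n = n,
          closures = labelClo[labels], kids = kids, desc = desc,
          parentsDesc = parentsDesc, grainCand = kids, mode = mode,
          roleCache = baseCache), envir = new.env(parent = emptyenv()))
        memo <- new.env(parent = emptyenv())
        if (!.tboxHolds(tbP, ctx, defs, memo)) next
        checked <- checked + 1
        res <- test(ctx, defs, memo, vocab[labels], edges)
        if (!is.null(res))
          return(list(result = res, checked = checked, capped = FALSE,
                      size = n))
      }
    }
  }
  list(result = NULL, checked = checked, capped = FALSE, size = maxSize)
}

.modelFromLabels <- function(labels, edges) {
  ids <- paste0("e", seq_along(labels))
  buildModel(stats::setNames(as.list(labels), ids),
             if (nrow(edges)) cbind(ids[edges[, 1L]], ids[edges[, 2L]])
             else NULL)
}

#' Bounded-model subsumption check
#'
#' Does every instance of `c` fall under `d` in every acyclic finite model
#' (up to `maxSize` entities, labelled from `vocab`) that satisfies the
#' TBox? Returns a [Verdict-class]: either bounded evidence that the
#' subsumption holds, or the first countermodel found together with the
#' witness entity.
#'
#' @param tb a [TBox-class]; equivalence axioms with an atomic side act as
#'   class definitions, remaining axioms as model admissibility constraints.
#' @param c,d class expressions or atomic class names.
#' @param registry a [TypeRegistry-class] for the atomic hierarchy.
#' @param vocab atomic types entities may be labelled with; defaults to the
#'   registry's plain types. Keep this to the signature of the problem:
#'   the search space is `|vocab|^n * 2^(n(n-1)/2)` per size `n`.
#' @param maxSize largest model size enumerated (default 4; the worked
#'   mixture patterns need no more than 5 entities, and exhaustive size-5
#'   runs are minutes-scale).
#' @param mode `"fol"` or `"primitive"`, see [classExtension()].
#' @param maxModels resource guard: stop after this many enumerated
#'   labelled graphs and return a partial (capped) verdict.
#' @return a [Verdict-class]
#' @export
boundedSubsumption <- function(tb, c, d, registry, vocab = NULL,
                               maxSize = 4L, mode = "fol",
                               maxModels = 5e6) {
  if (maxSize < 1L) .stopf("maxSize must be >= 1")
  cE <- .asExpr(c); dE <- .asExpr(d)
  if (is.null(vocab))
    vocab <- registry@typeTable$name[registry@typeTable$kind == "plain"]
  hit <- NULL
  out <- .searchModels(tb, registry, vocab, maxSize, mode, maxModels,
    test = function(ctx, defs, memo, labels, edges) {
      l <- .evalExpr(cE, ctx, defs, memo)
      r <- .evalExpr(dE, ctx, defs, memo)
      w <- which(l & !r)
      if (length(w)) list(labels = labels, edges = edges, witness = w[1L])
      else NULL
    })
  if (!is.null(out$result)) {
    cm <- .modelFromLabels(out$result$labels, out$result$edges)
    new("Verdict", holds = FALSE, countermodel = cm,
        counterexample = cm@entities[out$result$witness],
        maxSizeChecked = as.integer(out$size),
        modelsChecked = out$checked, capped = FALSE)
  } else {
    new("Verdict", holds = TRUE, countermodel = NULL,
        counterexample = character(),
        maxSizeChecked = as.integer(maxSize),
        modelsChecked = out$checked, capped = out$capped)
  }
}

#' Smallest finite model satisfying a class expression
#'
#' Enumerates models exactly as [boundedSubsumption()] does and returns the
#' first (hence minimal-size) admissible model in which the extension of
#' `expr` is non-empty.
#'
#' @inheritParams boundedSubsumption
#' @param expr class expression or atomic class name.
#' @return `list(model = FiniteModel, entity = id)` or `NULL` if no witness
#'   exists within the bound
#' @export
findMinimalWitness <- function(expr, tb, registry, vocab = NULL,
                               maxSize = 4L, mode = "fol",
                               maxModels = 5e6) {
  eE <- .asExpr(expr)
  if (is.null(vocab))
    vocab <- registry@typeTable$name[registry@typeTable$kind == "plain"]
  out <- .searchModels(tb, registry, vocab, maxSize, mode, maxModels,
    test = function(ctx, defs, memo, labels, edges) {
      v <- .evalExpr(eE, ctx, defs, memo)
      if (any(v)) list(labels = labels, edges = edges, witness = which(v)[1L])
      else NULL
    })
  if (is.null(out$result)) return(NULL)
  m <- .modelFromLabels(out$result$labels, out$result$edges)
  list(model = m, entity = m@entities[out$result$witness])
}
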