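# Small DAG helpers over integer-indexed edge lists. These sit in the
# model-enumeration hot loop, so they stay dependency-free and allocation-lean.

# children[[i]]: integer vector of direct successors of node i.
.childList <- function(edges, n) {
  kids <- vector("list", n)
  for (i in seq_len(n)) kids[[i]] <- integer(0)
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      w <- edges[k, 1L]
      kids[[w]] <- c(kids[[w]], edges[k, 2L])
    }
  }
  kids
}

# Transitive closure of a DAG given as a child list; returns a list of
# integer vectors (descendants, excluding self). Nodes are processed in
# reverse finishing order via an explicit stack so recursion depth never
# matters. Assumes acyclicity (checked separately).
.descClosure <- function(kids, n) {
  desc <- vector("list", n)
  done <- rep(FALSE, n)
  for (root in seq_len(n)) {
    if (done[root]) next
    stack <- root
    while (length(stack)) {
      v <- stack[length(stack)]
      pending <- kids[[v]][!done[kids[[v]]]]
      if (length(pending)) {
        stack <- c(stack, pending[1L])
      } else {
        d <- kids[[v]]
        if (length(d)) d <- unique(c(d, unlist(desc[d], use.names = FALSE)))
        desc[[v]] <- d
        done[v] <- TRUE
        stack <- stack[-length(stack)]
      }
    }
  }
  desc
}

# Returns the index of a node contained in its own descendant set, or 0L.
.findCycleNode <- function(edges, n) {
  if (!length(edges) || n == 0L) return(0L)
  # Kahn's algorithm: if a topological sort consumes all nodes, acyclic.
  indeg <- integer(n)
  for (k in seq_len(nrow(edges))) indeg[edges[k, 2L]] <- indeg[edges[k, 2L]] + 1L
  kids <- .childList(edges, n)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (u in kids[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) queue <- c(queue, u)
    }
  }
  if (seen == n) 0L else which(indeg > 0L)[1L]
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
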