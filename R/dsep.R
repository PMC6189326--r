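# d-separation in a DAG, and the derived perfect dependence oracle.
# Used to test structure search against ground-truth graphs, and available
# for constructing exact conditional-independence oracles.

# adjacency: t x t logical/0-1, TRUE at [i, j] means i -> j.

.dag_ancestors <- function(adj, nodes) {
  anc <- nodes
  repeat {
    pa <- which(rowSums(adj[, anc, drop = FALSE] != 0) > 0)
    new <- setdiff(pa, anc)
    if (length(new) == 0L) return(anc)
    anc <- c(anc, new)
  }
}

#' d-separation query on a DAG
#'
#' Tests whether nodes `a` and `b` are d-separated given the set `h`, via
#' the ancestral moral graph: restrict to ancestors of `{a, b} ∪ h`,
#' marry parents of common children, drop directions, remove `h`, and test
#' undirected connectivity.
#'
#' @param adj t x t adjacency matrix, nonzero at `[i, j]` for edge i -> j.
#' @param a,b node indices.
#' @param h conditioning node indices (may be empty).
#' @return TRUE if a and b are d-separated (conditionally independent in
#'   any distribution faithful to the DAG).
#' @export
dsep <- function(adj, a, b, h = integer(0)) {
  adj <- (as.matrix(adj) != 0) * 1L
  t <- nrow(adj)
  anc <- .dag_ancestors(adj, unique(c(a, b, h)))
  sub <- adj[anc, anc, drop = FALSE]
  m <- nrow(sub)
  und <- (sub + t(sub)) > 0
  # moralize: connect parents sharing a child
  for (child in seq_len(m)) {
    pa <- which(sub[, child] != 0)
    if (length(pa) > 1L)
      for (p1 in pa) und[p1, pa] <- TRUE
  }
  diag(und) <- FALSE
  keep <- !(anc %in% h)
  und <- und[keep, keep, drop = FALSE]
  ids <- anc[keep]
  ia <- match(a, ids); ib <- match(b, ids)
  if (is.na(ia) || is.na(ib)) return(TRUE)
  # BFS connectivity
  seen <- rep(FALSE, length(ids))
  queue <- ia; seen[ia] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(und[v, ] & !seen)
    if (ib %in% nb) return(FALSE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  TRUE
}

#' Perfect dependence oracle from a DAG
#'
#' Wraps [dsep()] as the oracle interface expected by [ic_algorithm()]:
#' two nodes are declared dependent exactly when they are d-connected.
#'
#' @param adj DAG adjacency matrix (i -> j at `[i, j]`).
#' @return function `(i, j, cond)` returning TRUE when dependent.
#' @export
dsep_oracle <- function(adj) {
  force(adj)
  function(i, j, cond) !dsep(adj, i, j, cond)
}
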