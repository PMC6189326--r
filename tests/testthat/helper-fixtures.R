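# Shared fixtures and independent oracles for the test suite.
# Expensive objects are memoized so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

fixture <- function(name, seed = 20181009L) {
  cached(paste0("fx_", name, "_", seed),
         suppressMessages(make_fixture(name, seed = seed)))
}

saturated_dag <- function(traits = c("y1", "y2", "y3")) {
  t <- length(traits)
  am <- matrix(0L, t, t)
  am[upper.tri(am)] <- 2L
  semgwas:::causal_structure(traits, am, status = "dag")
}

chain_dag <- function(traits = c("y1", "y2", "y3")) {
  t <- length(traits)
  am <- matrix(0L, t, t)
  for (i in seq_len(t - 1L)) am[i, i + 1L] <- 2L
  semgwas:::causal_structure(traits, am, status = "dag")
}

empty_dag <- function(traits = c("y1", "y2", "y3")) {
  t <- length(traits)
  semgwas:::causal_structure(traits, matrix(0L, t, t), status = "dag")
}

# Brute-force HPD oracle: scan every window of ceiling(cov * S) sorted
# draws, independent of the package implementation.
hpd_brute <- function(x, coverage) {
  x <- sort(x)
  S <- length(x)
  m <- ceiling(coverage * S)
  best <- NULL
  for (i in seq_len(S - m + 1L)) {
    w <- x[i + m - 1L] - x[i]
    if (is.null(best) || w < best$w) best <- list(i = i, w = w)
  }
  c(x[best$i], x[best$i + m - 1L])
}

# All DAGs on `t` labeled nodes, as a list of adjacency matrices
# (enumerate every orientation of every edge subset, keep the acyclic).
all_dags <- function(t) {
  pairs <- utils::combn(t, 2L)
  n_pair <- ncol(pairs)
  out <- list()
  states <- expand.grid(rep(list(0:2), n_pair))  # 0 none, 1 i->j, 2 j->i
  is_acyclic <- function(adj) {
    reach <- adj
    for (k in seq_len(t)) reach <- (reach %*% adj + reach) > 0
    !any(diag(reach) > 0)
  }
  for (r in seq_len(nrow(states))) {
    adj <- matrix(0, t, t)
    for (e in seq_len(n_pair)) {
      s <- states[r, e]
      if (s == 1) adj[pairs[1L, e], pairs[2L, e]] <- 1
      if (s == 2) adj[pairs[2L, e], pairs[1L, e]] <- 1
    }
    if (is_acyclic(adj)) out[[length(out) + 1L]] <- adj
  }
  out
}

# True v-structures of a DAG: unordered parent pairs a, b with a common
# child c, a and b non-adjacent.
true_vstructures <- function(adj) {
  t <- nrow(adj)
  out <- character(0)
  for (cc in seq_len(t)) {
    pa <- which(adj[, cc] != 0)
    if (length(pa) < 2L) next
    for (pr in utils::combn(pa, 2L, simplify = FALSE)) {
      if (adj[pr[1L], pr[2L]] == 0 && adj[pr[2L], pr[1L]] == 0)
        out <- c(out, paste(sort(pr), cc, sep = "-"))
    }
  }
  sort(out)
}

# v-structures present in an IC result (directed a -> c <- b, a, b
# non-adjacent).
found_vstructures <- function(struct) {
  am <- struct$amat
  t <- nrow(am)
  out <- character(0)
  for (cc in seq_len(t)) {
    pa <- which(am[, cc] == 2L)
    if (length(pa) < 2L) next
    for (pr in utils::combn(pa, 2L, simplify = FALSE)) {
      if (am[pr[1L], pr[2L]] == 0L && am[pr[2L], pr[1L]] == 0L)
        out <- c(out, paste(sort(pr), cc, sep = "-"))
    }
  }
  sort(out)
}

skeleton_of <- function(x) {
  am <- if (inherits(x, "causal_structure")) {
    (x$amat + t(x$amat)) > 0
  } else {
    (x + t(x)) > 0
  }
  unname(am)
}

random_dag_lambda <- function(t, seed_offset = 0L) {
  L <- matrix(0, t, t)
  mask <- rbinom(t * (t - 1L) / 2L, 1L, 0.6)
  L[lower.tri(L)] <- rnorm(t * (t - 1L) / 2L, sd = 0.6) * mask
  L
}
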