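# Phenotypic causal network search: residual partial correlations, HPD
# decisions, the inductive-causation (IC) algorithm, and DAG completion.

#' Partial correlation from a covariance matrix
#'
#' Partial correlation of a trait pair given a conditioning set, computed
#' from the inverse of the covariance submatrix over the pair plus the
#' conditioning traits. An empty conditioning set yields the marginal
#' correlation.
#'
#' @param sigma t x t covariance matrix (e.g. one posterior draw of the
#'   residual covariance).
#' @param pair length-2 vector of trait indices or names.
#' @param conditioning vector of trait indices/names (may be empty).
#' @return partial correlation (scalar).
#' @export
residual_partial_correlation <- function(sigma, pair, conditioning = integer(0)) {
  sigma <- as.matrix(sigma)
  idx <- function(x) if (is.character(x)) match(x, colnames(sigma)) else as.integer(x)
  pair <- idx(pair); conditioning <- idx(conditioning)
  if (length(pair) != 2L || anyNA(pair)) .stopf("pair must name two traits")
  if (any(pair %in% conditioning))
    .stopf("conditioning set must exclude the pair")
  sub <- c(pair, conditioning)
  S <- sigma[sub, sub, drop = FALSE]
  P <- tryCatch(solve(S), error = function(e)
    .stopf("singular covariance submatrix over traits %s",
           paste(sub, collapse = ",")))
  -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
}

#' Partial-correlation draws across stored covariance draws
#'
#' Applies [residual_partial_correlation()] to every stored draw of the
#' chosen covariance component, yielding the posterior sample of the
#' partial correlation that the HPD dependence decisions are based on.
#'
#' @param draws a `posterior_draws` object.
#' @inheritParams residual_partial_correlation
#' @param component `"sigma_e"` (residual, the network-search default) or
#'   `"sigma_g"`.
#' @return numeric vector, one partial correlation per stored draw.
#' @export
partial_correlation_draws <- function(draws, pair, conditioning = integer(0),
                                      component = c("sigma_e", "sigma_g")) {
  component <- match.arg(component)
  arr <- draws[[component]]
  vapply(seq_len(dim(arr)[1L]), function(s)
    residual_partial_correlation(arr[s, , ], pair, conditioning), numeric(1))
}

#' Highest posterior density interval
#'
#' Shortest contiguous window of the sorted draws containing
#' `ceiling(coverage * S)` of the S draws; ties are broken by the lowest
#' starting index.
#'
#' @param samples numeric draws (at least 10).
#' @param coverage fraction in (0, 1).
#' @return list with `lower`, `upper`, `coverage`.
#' @export
hpd_interval <- function(samples, coverage = 0.95) {
  stopifnot(length(samples) >= 10L, coverage > 0, coverage < 1)
  x <- sort(samples)
  S <- length(x)
  m <- ceiling(coverage * S)
  starts <- seq_len(S - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]   # which.min takes the first minimum
  list(lower = x[i], upper = x[i + m - 1L], coverage = coverage)
}

#' HPD dependence decision
#'
#' Declares a trait pair conditionally dependent when the HPD interval of
#' the partial-correlation draws does not contain zero.
#'
#' @param samples draws of a partial correlation.
#' @param coverage HPD coverage.
#' @return `"dependent"` or `"independent"`.
#' @export
dependence_decision <- function(samples, coverage = 0.95) {
  h <- hpd_interval(samples, coverage)
  if (h$lower > 0 || h$upper < 0) "dependent" else "independent"
}

# ---- causal structure container ----------------------------------------

# amat codes: 0 no edge, 1 undirected (symmetric), 2 directed row -> col.
causal_structure <- function(traits, amat, sepsets = list(),
                             status = "pdag", decisions = NULL) {
  dimnames(amat) <- list(traits, traits)
  structure(list(traits = traits, amat = amat, sepsets = sepsets,
                 status = status, lambda = NULL, decisions = decisions),
            class = "causal_structure")
}

#' Edge list of a causal structure
#' @param x a `causal_structure`.
#' @return data.frame with columns from, to, status (directed/undirected);
#'   undirected edges are listed once with from < to.
#' @export
structure_edges <- function(x) {
  am <- x$amat
  t <- length(x$traits)
  out <- list()
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (i < j && am[i, j] == 1L)
      out[[length(out) + 1L]] <- data.frame(from = x$traits[i],
                                            to = x$traits[j],
                                            status = "undirected")
    if (am[i, j] == 2L)
      out[[length(out) + 1L]] <- data.frame(from = x$traits[i],
                                            to = x$traits[j],
                                            status = "directed")
  }
  if (length(out) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      status = character(0)))
  do.call(rbind, out)
}

#' @export
print.causal_structure <- function(x, ...) {
  cat("causal_structure (", x$status, ") over: ",
      paste(x$traits, collapse = ", "), "\n", sep = "")
  e <- structure_edges(x)
  if (nrow(e) == 0L) cat("  (no edges)\n")
  else for (i in seq_len(nrow(e)))
    cat("  ", e$from[i], if (e$status[i] == "directed") " -> " else " -- ",
        e$to[i], "\n", sep = "")
  if (!is.null(x$lambda)) {
    cat("  structural coefficients:\n")
    print(round(x$lambda, 4))
  }
  invisible(x)
}

.adjacent <- function(am, i) which(am[i, ] != 0L | am[, i] != 0L)

.subsets_of <- function(v) {
  # all subsets of v by increasing size (combn would misread a scalar v)
  if (length(v) == 0L) return(list(integer(0)))
  if (length(v) == 1L) return(list(integer(0), as.integer(v)))
  out <- list(integer(0))
  for (k in seq_along(v))
    out <- c(out, utils::combn(as.integer(v), k, simplify = FALSE))
  out
}

#' Inductive-causation (IC) algorithm
#'
#' Infers a partially directed acyclic graph over the traits from an oracle
#' of conditional (in)dependence decisions: (i) the skeleton keeps an edge
#' between two traits only if no conditioning subset of the remaining
#' traits renders them independent (the first separating subset, by
#' increasing size, is recorded); (ii) every triple a - c - b with a, b
#' non-adjacent is oriented a -> c <- b when c is not in the recorded
#' separating set; (iii) the standard orientation-propagation rules are
#' applied to closure. Conditioning subsets are enumerated exhaustively, so
#' the trait count is limited to 10.
#'
#' @param traits character vector of trait names (t <= 10).
#' @param oracle function `(i, j, cond)` over trait indices returning TRUE
#'   if traits i and j are dependent given the conditioning index set.
#' @return A `causal_structure` with status `"pdag"`.
#' @export
ic_algorithm <- function(traits, oracle) {
  t <- length(traits)
  if (t > 10L) .stopf("exhaustive subset search limited to 10 traits")
  am <- matrix(1L, t, t); diag(am) <- 0L
  sepsets <- list()
  decisions <- list()
  # skeleton
  for (i in seq_len(t - 1L)) for (j in (i + 1L):t) {
    rest <- setdiff(seq_len(t), c(i, j))
    for (h in .subsets_of(rest)) {
      dep <- isTRUE(oracle(i, j, h))
      decisions[[length(decisions) + 1L]] <- list(
        pair = c(traits[i], traits[j]), conditioning = traits[h],
        decision = if (dep) "dependent" else "independent")
      if (!dep) {
        am[i, j] <- am[j, i] <- 0L
        sepsets[[paste(i, j, sep = "|")]] <- h
        break
      }
    }
  }
  # v-structures: a -> c <- b for non-adjacent a, b with common neighbour c
  for (a in seq_len(t - 1L)) for (b in (a + 1L):t) {
    if (am[a, b] != 0L || am[b, a] != 0L) next
    key <- paste(a, b, sep = "|")
    if (is.null(sepsets[[key]])) next
    common <- intersect(.adjacent(am, a), .adjacent(am, b))
    for (cc in setdiff(common, sepsets[[key]])) {
      for (parent in c(a, b)) {
        if (am[cc, parent] == 2L)
          .stopf("contradictory orientations at triple %s -> %s <- %s",
                 traits[a], traits[cc], traits[b])
        am[parent, cc] <- 2L
        am[cc, parent] <- 0L
      }
    }
  }
  am <- .meek_closure(am, traits)
  causal_structure(traits, am, sepsets, "pdag", decisions)
}

# Orientation-propagation (Meek) rules, applied to closure:
#  R1: a -> b - c with a, c non-adjacent        => b -> c
#  R2: a -> b -> c with a - c                   => a -> c
#  R3: a - b, a - c -> b, a - d -> b, c, d non-adjacent => a -> b
.meek_closure <- function(am, traits) {
  t <- nrow(am)
  repeat {
    changed <- FALSE
    orient <- function(i, j) {
      if (am[j, i] == 2L)
        .stopf("contradictory orientations forced between %s and %s",
               traits[i], traits[j])
      am[i, j] <<- 2L; am[j, i] <<- 0L; changed <<- TRUE
    }
    for (b in seq_len(t)) for (cc in seq_len(t)) {
      if (am[b, cc] != 1L) next   # undirected b - cc
      # R1
      pa <- which(am[, b] == 2L)
      if (any(am[pa, cc] == 0L & am[cc, pa] == 0L)) { orient(b, cc); next }
      # R2 (a = b, c = cc): directed path b -> x -> cc with b - cc
      mid <- which(am[b, ] == 2L & am[, cc] == 2L)
      if (length(mid) > 0L) { orient(b, cc); next }
      # R3
      into <- which(am[, cc] == 2L & (am[b, ] == 1L | am[, b] == 1L))
      into <- into[am[b, into] == 1L]
      if (length(into) >= 2L) {
        pairs <- utils::combn(into, 2L)
        nonadj <- apply(pairs, 2L, function(pr)
          am[pr[1L], pr[2L]] == 0L && am[pr[2L], pr[1L]] == 0L)
        if (any(nonadj)) { orient(b, cc); next }
      }
    }
    if (!changed) break
  }
  am
}

#' Complete a PDAG to a DAG with a causal order
#'
#' The IC output can leave edges undirected (e.g. a complete skeleton with
#' no v-structures). This orients every undirected edge a - b as a -> b
#' when a precedes b in the supplied order; existing directed edges must be
#' consistent with the order.
#'
#' @param pdag a `causal_structure`.
#' @param order character vector, a permutation of the traits.
#' @return A `causal_structure` with status `"dag"`.
#' @export
orient_with_order <- function(pdag, order) {
  stopifnot(inherits(pdag, "causal_structure"))
  if (!setequal(order, pdag$traits) || length(order) != length(pdag$traits))
    .stopf("order must be a permutation of the traits")
  pos <- match(pdag$traits, order)
  am <- pdag$amat
  t <- nrow(am)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (am[i, j] == 2L && pos[i] > pos[j])
      .stopf("directed edge %s -> %s contradicts the causal order",
             pdag$traits[i], pdag$traits[j])
  }
  for (i in seq_len(t - 1L)) for (j in (i + 1L):t) {
    if (am[i, j] == 1L) {
      if (pos[i] < pos[j]) { am[i, j] <- 2L; am[j, i] <- 0L }
      else { am[j, i] <- 2L; am[i, j] <- 0L }
    }
  }
  out <- causal_structure(pdag$traits, am, pdag$sepsets, "dag",
                          pdag$decisions)
  out$order <- order
  out
}

#' Infer a causal structure from posterior covariance draws
#'
#' Builds the IC dependence oracle from the stored residual-covariance
#' draws: for each queried pair and conditioning set the posterior draws of
#' the residual partial correlation are summarized by an HPD interval, and
#' dependence is declared when the interval excludes zero.
#'
#' @param draws a `posterior_draws` object.
#' @param hpd HPD coverage (the study grid is 0.75, 0.85, 0.95).
#' @param component which covariance to query (residual by default).
#' @return A `causal_structure` (PDAG) carrying the per-query decisions.
#' @export
infer_structure <- function(draws, hpd = 0.85, component = "sigma_e") {
  traits <- draws$traits
  oracle <- function(i, j, cond) {
    rho <- partial_correlation_draws(draws, c(i, j), cond, component)
    dependence_decision(rho, hpd) == "dependent"
  }
  out <- ic_algorithm(traits, oracle)
  out$hpd <- hpd
  out
}

#' Serialize a causal structure
#'
#' Writes the edge list as TSV (`from`, `to`, `status`, and the structural
#' coefficient when present) plus a JSON sidecar with separating sets, HPD
#' level and the per-query decisions.
#'
#' @param x a `causal_structure`.
#' @param path TSV path; the sidecar gets extension `.json`.
#' @export
write_structure <- function(x, path) {
  e <- structure_edges(x)
  if (!is.null(x$lambda) && nrow(e) > 0L) {
    e$coefficient <- NA_real_
    for (i in seq_len(nrow(e)))
      if (e$status[i] == "directed")
        e$coefficient[i] <- x$lambda[e$to[i], e$from[i]]
  }
  data.table::fwrite(e, path, sep = "\t", na = "NA")
  side <- list(traits = x$traits, status = x$status, hpd = x$hpd,
               sepsets = lapply(x$sepsets, function(h) x$traits[h]),
               decisions = x$decisions)
  jsonlite::write_json(side, paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
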