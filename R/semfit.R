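# Structural equation mixed model: joint REML fit of structural
# coefficients, genetic covariance and diagonal residual variances.

# Edge list (parent -> child index pairs) of a DAG structure.
.dag_edges <- function(dag) {
  if (!inherits(dag, "causal_structure") || dag$status != "dag")
    .stopf("a completed DAG is required (see orient_with_order())")
  if (any(dag$amat == 1L)) .stopf("DAG still contains undirected edges")
  which(dag$amat == 2L, arr.ind = TRUE)  # [ ,1] parent, [ ,2] child
}

.lambda_from_edges <- function(edges, values, t) {
  L <- matrix(0, t, t)
  if (nrow(edges) > 0L)
    L[cbind(edges[, 2L], edges[, 1L])] <- values  # Lambda[child, parent]
  L
}

# Topological-order check: Lambda must be permutable to strictly lower
# triangular, i.e. the DAG acyclic. Kahn's algorithm on the edge set.
.check_acyclic <- function(edges, t, traits) {
  adj <- matrix(FALSE, t, t)
  if (nrow(edges) > 0L) adj[cbind(edges[, 1L], edges[, 2L])] <- TRUE
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  while (length(avail) > 0L) {
    v <- avail[1L]; avail <- avail[-1L]
    order <- c(order, v)
    ch <- which(adj[v, ])
    adj[v, ch] <- FALSE
    indeg[ch] <- indeg[ch] - 1L
    avail <- c(avail, ch[indeg[ch] == 0L & !(ch %in% order)])
  }
  if (length(order) < t)
    .stopf("cyclic structure over traits: %s",
           paste(traits[setdiff(seq_len(t), order)], collapse = ", "))
  order
}

#' Fit a structural equation mixed model by REML
#'
#' Recursive system Y = Y Lambda' + 1 mu' + g + e on the structural scale,
#' with vec(g) ~ N(0, Sigma_g (x) K) and independent trait residuals
#' (diagonal Psi) -- the restriction that renders the structural
#' coefficients likelihood-identifiable. Estimation maximizes the
#' restricted likelihood of the reduced form, whose genetic and residual
#' covariances are B Sigma_g B' and B Psi B' with B = (I - Lambda)^-1, over
#' the structural coefficients (one per DAG edge), the full genetic
#' covariance and the residual variances. Standard errors come from the
#' observed information at the optimum.
#'
#' @param pheno data.frame of traits.
#' @param K a `kinship_matrix`.
#' @param dag a `causal_structure` with status `"dag"` whose traits match
#'   the phenotype columns.
#' @param mtm optional `mtm_fit` on the same data used to initialize the
#'   covariance parameters (and, for a fully recursive DAG, the structural
#'   coefficients, via the exact reparameterization).
#' @param residual_covariance must be `"diagonal"`; requesting an
#'   unstructured residual covariance is refused because it would leave the
#'   structural coefficients unidentifiable.
#' @param genetic_covariance `"unstructured"` (default: cross-trait genetic
#'   covariances retained) or `"diagonal"` (independent polygenic effects,
#'   under which an empty DAG factorizes into single-trait models).
#' @return A `sem_fit`: `lambda` (t x t matrix), `lambda_se`,
#'   `lambda_cov`, `sigma_g`, `psi`, restricted `logL`,
#'   `k = edges + t(t+1)/2 + t`, and bookkeeping fields.
#' @export
fit_sem <- function(pheno, K, dag, mtm = NULL,
                    residual_covariance = c("diagonal", "unstructured"),
                    genetic_covariance = c("unstructured", "diagonal")) {
  residual_covariance <- match.arg(residual_covariance)
  genetic_covariance <- match.arg(genetic_covariance)
  if (residual_covariance != "diagonal")
    .stopf(paste("non-diagonal residual covariance refused: independent",
                 "trait residuals are required to render structural",
                 "coefficients likelihood-identifiable"))
  dat <- .prepare_mtm_data(pheno, K)
  t <- ncol(dat$Y)
  traits <- colnames(dat$Y)
  if (!setequal(dag$traits, traits))
    .stopf("DAG traits do not match phenotype columns")
  # reindex DAG edges to phenotype column order
  perm <- match(traits, dag$traits)
  am <- dag$amat[perm, perm, drop = FALSE]
  edges <- which(am == 2L, arr.ind = TRUE)
  if (any(am == 1L)) .stopf("DAG still contains undirected edges")
  .check_acyclic(edges, t, traits)
  n_edge <- nrow(edges)

  ct <- .contrast_transform(dat$Y, dat$K)

  # Initial covariance components from (or via) the multi-trait model.
  if (is.null(mtm)) {
    em <- .em_2comp(ct$Z, ct$d, maxit = 200L, tol = 1e-8)
    Sg_M <- em$sigma_g; Se_M <- em$sigma_e
  } else {
    Sg_M <- mtm$sigma_g; Se_M <- mtm$sigma_e
  }
  # Initialize each child's coefficients by the population regression of
  # the reduced-form residual covariance on its parents; for a fully
  # recursive DAG this is the exact reparameterization of the MTM.
  lam0 <- numeric(n_edge)
  L0 <- matrix(0, t, t)
  for (child in seq_len(t)) {
    pa <- edges[edges[, 2L] == child, 1L]
    if (length(pa) == 0L) next
    beta <- solve(Se_M[pa, pa, drop = FALSE], Se_M[pa, child])
    L0[child, pa] <- beta
  }
  if (n_edge > 0L) lam0 <- L0[cbind(edges[, 2L], edges[, 1L])]
  IL0 <- diag(t) - L0
  Sg0 <- .sym(IL0 %*% Sg_M %*% t(IL0))
  psi0 <- pmax(diag(IL0 %*% Se_M %*% t(IL0)), 1e-6)

  diag_g <- genetic_covariance == "diagonal"
  np_g <- if (diag_g) t else .logchol_npar(t)
  pack <- function(lam, Sg, psi) {
    gpar <- if (diag_g) log(pmax(diag(Sg), 1e-10))
            else .logchol_pack(Sg + diag(1e-10, t))
    c(lam, gpar, log(psi))
  }
  unpack <- function(par) {
    lam <- if (n_edge > 0L) par[seq_len(n_edge)] else numeric(0)
    Sg <- if (diag_g) diag(exp(par[n_edge + seq_len(np_g)]), t)
          else .logchol_unpack(par[n_edge + seq_len(np_g)], t)
    psi <- exp(par[n_edge + np_g + seq_len(t)])
    list(lam = lam, Sg = Sg, psi = psi)
  }
  negll <- function(par) {
    pr <- unpack(par)
    Lam <- .lambda_from_edges(edges, pr$lam, t)
    B <- tryCatch(solve(diag(t) - Lam), error = function(e) NULL)
    if (is.null(B)) return(1e10)
    A <- .sym(B %*% pr$Sg %*% t(B))
    C <- .sym(B %*% diag(pr$psi, t) %*% t(B))
    ll <- .loglik2(A, C, ct$d, ct$Z)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  par0 <- pack(lam0, Sg0, psi0)
  npar <- length(par0)
  lower <- c(rep(-Inf, n_edge), rep(-20, np_g), rep(-20, t))
  upper <- c(rep(Inf, n_edge), rep(20, np_g), rep(20, t))
  opt <- optim(par0, negll, method = "L-BFGS-B", lower = lower,
               upper = upper, control = list(maxit = 500L, factr = 1e3))
  pr <- unpack(opt$par)
  Lam <- .lambda_from_edges(edges, pr$lam, t)
  dimnames(Lam) <- list(traits, traits)

  lambda_se <- matrix(NA_real_, t, t, dimnames = dimnames(Lam))
  lambda_cov <- NULL
  if (n_edge > 0L) {
    H <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
    if (!is.null(H)) {
      Vp <- tryCatch(solve(.sym(H)), error = function(e) NULL)
      if (!is.null(Vp)) {
        lambda_cov <- Vp[seq_len(n_edge), seq_len(n_edge), drop = FALSE]
        se <- sqrt(pmax(diag(lambda_cov), 0))
        lambda_se[cbind(edges[, 2L], edges[, 1L])] <- se
      }
    }
  }
  edge_df <- if (n_edge > 0L)
    data.frame(from = traits[edges[, 1L]], to = traits[edges[, 2L]],
               lambda = pr$lam,
               se = lambda_se[cbind(edges[, 2L], edges[, 1L])])
  else data.frame(from = character(0), to = character(0),
                  lambda = numeric(0), se = numeric(0))

  structure(list(
    lambda = Lam, lambda_se = lambda_se, lambda_cov = lambda_cov,
    edges = edge_df,
    sigma_g = .sym(pr$Sg), psi = pr$psi,
    logL = -opt$value,
    k = n_edge + (if (diag_g) t else t * (t + 1L) / 2L) + t,
    n_records = nrow(dat$Y), traits = traits,
    dag = dag, kinship_kind = attr(dat$K, "kind"),
    samples = dat$ids,
    convergence = opt$convergence,
    fingerprint = .data_fingerprint(dat$Y)
  ), class = c("sem_fit", "mixed_model_fit"))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Structural equation mixed model (REML), traits:",
      paste(x$traits, collapse = ", "), "\n")
  cat(sprintf("  n = %d, logL = %.4f, k = %d\n", x$n_records, x$logL, x$k))
  if (nrow(x$edges) > 0L) {
    cat("  structural coefficients:\n")
    for (i in seq_len(nrow(x$edges)))
      cat(sprintf("    %s -> %s: %.4f (se %.4f)\n", x$edges$from[i],
                  x$edges$to[i], x$edges$lambda[i], x$edges$se[i]))
  } else cat("  (no structural edges)\n")
  cat("  residual variances (psi):", sprintf("%.4f", x$psi), "\n")
  invisible(x)
}
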