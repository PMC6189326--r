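# SNP scan under the structural model, and the decomposition of SNP
# effects into direct, per-path indirect, and total components.

#' Per-SNP scan of direct effects under a fitted SEM
#'
#' Each marker is entered separately into the structural system with the
#' structural coefficients and variance components held fixed at the
#' no-SNP estimates. The marker's trait-wise effects are estimated jointly
#' by generalized least squares on the reduced form (covariance
#' B Sigma_g B' (x) K + B Psi B' (x) I); the reduced-form coefficients are
#' the total effects, and premultiplication by (I - Lambda) returns the
#' direct effects reported here.
#'
#' @param pheno data.frame of traits.
#' @param g a `genotype_matrix` (missing dosages mean-imputed).
#' @param K a `kinship_matrix`.
#' @param fit a `sem_fit` from the no-SNP model.
#' @return A `snp_scan` data.frame of direct effects (snp, chrom, pos,
#'   trait, estimate, se, t, p), with the matching total effects attached
#'   as attribute `"total"`.
#' @export
sem_snp_scan <- function(pheno, g, K, fit) {
  dat <- .prepare_mtm_data(pheno, K)
  stopifnot(identical(colnames(dat$Y), fit$traits))
  g <- impute_dosages(g)
  if (!all(dat$ids %in% rownames(g$dosages)))
    .stopf("genotypes missing for some phenotyped samples")
  W <- g$dosages[dat$ids, , drop = FALSE]
  t <- length(fit$traits)
  IL <- diag(t) - fit$lambda
  B <- solve(IL)
  A <- .sym(B %*% fit$sigma_g %*% t(B))
  C <- .sym(B %*% diag(fit$psi, t) %*% t(B))
  eig <- K_eigen(dat$K)
  res <- .gls_scan(dat$Y, W, eig, A, C)
  mono <- apply(W, 2L, function(x) var(x) == 0)
  res$est[mono, ] <- NA_real_
  res$var[mono, ] <- NA_real_
  # totals are the reduced-form coefficients; direct = (I - Lambda) total
  Mdir <- res$Rinv %*% t(IL)
  direct <- res$est %*% t(IL)
  vdir <- res$Vgam %*% Mdir^2
  vdir[mono, ] <- NA_real_
  out <- .scan_result(g, direct, vdir, fit$traits)
  tot <- .scan_result(g, res$est, res$var, fit$traits)
  attr(out, "total") <- tot
  attr(out, "lambda") <- fit$lambda
  out
}

# Directed children of each node under Lambda (Lambda[child, parent]).
.lambda_children <- function(Lambda) {
  lapply(seq_len(ncol(Lambda)), function(p) which(Lambda[, p] != 0))
}

#' Enumerate indirect paths from a SNP to a target trait
#'
#' All directed paths from every trait with a nonzero direct SNP effect to
#' the target; each path contributes the product of the structural
#' coefficients along it times the direct effect at its head. The target's
#' own direct effect is not a path.
#'
#' @param dag a `causal_structure` (status `"dag"`); may be NULL, in which
#'   case the nonzero pattern of `Lambda` defines the graph.
#' @param Lambda t x t structural coefficient matrix (`[child, parent]`).
#' @param direct numeric t-vector of direct SNP effects per trait.
#' @param target target trait index or name.
#' @return data.frame with columns `path` (e.g. `"y1->y2->y3"`) and
#'   `contribution`; zero rows when no indirect path exists.
#' @export
enumerate_indirect_paths <- function(dag = NULL, Lambda, direct, target) {
  t <- ncol(Lambda)
  traits <- colnames(Lambda)
  if (is.null(traits)) traits <- paste0("y", seq_len(t))
  if (is.character(target)) target <- match(target, traits)
  adj <- if (!is.null(dag)) {
    perm <- if (setequal(dag$traits, traits)) match(traits, dag$traits)
            else seq_len(t)
    t(dag$amat[perm, perm, drop = FALSE] == 2L) * 1
  } else (Lambda != 0) * 1
  # adj[child, parent] nonzero; walk child links parent -> child
  paths <- list()
  walk <- function(node, trail) {
    if (node == target && length(trail) > 1L) {
      paths[[length(paths) + 1L]] <<- trail
      return(invisible())
    }
    for (child in which(adj[, node] != 0))
      if (!(child %in% trail)) walk(child, c(trail, child))
  }
  for (u in setdiff(which(direct != 0), target)) walk(u, u)
  if (length(paths) == 0L)
    return(data.frame(path = character(0), contribution = numeric(0)))
  data.frame(
    path = vapply(paths, function(p) paste(traits[p], collapse = "->"),
                  character(1)),
    contribution = vapply(paths, function(p) {
      lam <- prod(Lambda[cbind(p[-1L], p[-length(p)])])
      lam * direct[p[1L]]
    }, numeric(1))
  )
}

#' Total effects from the reduced form
#'
#' T = (I - Lambda)^-1 d: the matrix-inverse route to the total SNP
#' effects, used as the independent oracle for the path-sum decomposition.
#'
#' @param Lambda t x t structural coefficient matrix.
#' @param direct numeric t-vector of direct effects.
#' @return numeric t-vector of total effects.
#' @export
total_effect_reduced_form <- function(Lambda, direct) {
  t <- ncol(Lambda)
  B <- tryCatch(solve(diag(t) - Lambda), error = function(e)
    .stopf("singular (I - Lambda); the structure is not invertible"))
  as.numeric(B %*% direct)
}

#' Decompose one SNP's effects into direct, indirect and total
#'
#' Point estimates follow the path rules: the indirect effect on a trait is
#' the sum over all directed paths into it of the path's coefficient
#' product times the upstream direct effect, and the total is direct plus
#' indirect. Standard errors of indirect and total effects use a
#' first-order delta method over the direct effects (taken independent
#' across traits) and the structural coefficients (with their estimation
#' covariance when supplied), treating the two blocks as independent.
#'
#' @param dag a `causal_structure` DAG (or NULL to take the graph from the
#'   nonzero pattern of `Lambda`).
#' @param Lambda t x t structural coefficients (`[child, parent]`).
#' @param direct numeric t-vector of direct effects.
#' @param se_direct numeric t-vector of their standard errors.
#' @param lambda_edges optional data.frame `from`, `to` listing the free
#'   coefficients in the order matching `cov_lambda` (as in a `sem_fit`).
#' @param cov_lambda optional covariance matrix of the free coefficients.
#' @return An `effect_decomposition`: per-trait data.frame with estimate,
#'   se, t and p for each of direct/indirect/total, plus the per-path
#'   contribution list.
#' @export
decompose_snp_effect <- function(dag = NULL, Lambda, direct,
                                 se_direct = rep(NA_real_, length(direct)),
                                 lambda_edges = NULL, cov_lambda = NULL) {
  t <- ncol(Lambda)
  traits <- colnames(Lambda)
  if (is.null(traits)) traits <- paste0("y", seq_len(t))
  dimnames(Lambda) <- list(traits, traits)
  B <- solve(diag(t) - Lambda)      # used for delta-method gradients only
  Bd <- as.numeric(B %*% direct)
  paths <- lapply(seq_len(t), function(tt)
    enumerate_indirect_paths(dag, Lambda, direct, tt))
  ind <- vapply(paths, function(p) sum(p$contribution), numeric(1))
  total <- direct + ind

  var_total <- var_ind <- rep(NA_real_, t)
  if (!anyNA(se_direct)) {
    for (tt in seq_len(t)) {
      gd_tot <- B[tt, ]                      # d T_t / d d
      gd_ind <- gd_tot - as.numeric(seq_len(t) == tt)
      v_tot <- sum(gd_tot^2 * se_direct^2)
      v_ind <- sum(gd_ind^2 * se_direct^2)
      if (!is.null(cov_lambda) && !is.null(lambda_edges) &&
          nrow(lambda_edges) > 0L) {
        gl <- vapply(seq_len(nrow(lambda_edges)), function(e) {
          u <- match(lambda_edges$from[e], traits)
          v <- match(lambda_edges$to[e], traits)
          # d T_t / d lambda_{v<-u} = B[t, v] * (B d)[u]
          B[tt, v] * Bd[u]
        }, numeric(1))
        v_lam <- as.numeric(t(gl) %*% cov_lambda %*% gl)
        v_tot <- v_tot + v_lam
        v_ind <- v_ind + v_lam
      }
      var_total[tt] <- v_tot
      var_ind[tt] <- v_ind
    }
  }
  tab <- data.frame(
    trait = rep(traits, 3L),
    effect_type = rep(c("direct", "indirect", "total"), each = t),
    estimate = c(direct, ind, total),
    se = sqrt(c(se_direct^2, var_ind, var_total))
  )
  tab$t <- tab$estimate / tab$se
  tab$p <- 2 * pnorm(-abs(tab$t))
  structure(list(table = tab, paths = setNames(paths, traits),
                 lambda = Lambda),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Decompose every SNP of a scan
#'
#' Applies [decompose_snp_effect()] across a direct-effect scan, adds
#' Benjamini-Hochberg q-values per effect type, and returns the long,
#' Manhattan-ready table (one row per SNP x trait x effect type, with the
#' contributing paths of indirect rows joined by `";"`).
#'
#' @param fit the `sem_fit` whose coefficients the scan used.
#' @param scan a direct-effect `snp_scan` from [sem_snp_scan()].
#' @return data.frame with columns snp, chrom, pos, trait, effect_type,
#'   estimate, se, t, p, q, paths.
#' @export
decompose_scan <- function(fit, scan) {
  traits <- fit$traits
  t <- length(traits)
  wide_est <- matrix(scan$estimate, ncol = t)
  wide_se <- matrix(scan$se, ncol = t)
  snps <- scan$snp[seq_len(nrow(wide_est))]
  chrom <- scan$chrom[seq_len(nrow(wide_est))]
  pos <- scan$pos[seq_len(nrow(wide_est))]
  rows <- vector("list", nrow(wide_est))
  for (j in seq_len(nrow(wide_est))) {
    if (anyNA(wide_est[j, ])) {
      rows[[j]] <- data.frame(trait = rep(traits, 3L),
                              effect_type = rep(c("direct", "indirect",
                                                  "total"), each = t),
                              estimate = NA_real_, se = NA_real_,
                              t = NA_real_, p = NA_real_,
                              paths = NA_character_)
      next
    }
    dec <- decompose_snp_effect(fit$dag, fit$lambda, wide_est[j, ],
                                wide_se[j, ],
                                lambda_edges = fit$edges,
                                cov_lambda = fit$lambda_cov)
    tab <- dec$table
    tab$paths <- NA_character_
    idx_ind <- which(tab$effect_type == "indirect")
    tab$paths[idx_ind] <- vapply(traits, function(tr) {
      p <- dec$paths[[tr]]
      if (nrow(p) == 0L) "" else paste(p$path, collapse = ";")
    }, character(1))
    rows[[j]] <- tab
  }
  out <- do.call(rbind, rows)
  out <- data.frame(snp = rep(snps, each = 3L * t),
                    chrom = rep(chrom, each = 3L * t),
                    pos = rep(pos, each = 3L * t), out)
  out$q <- NA_real_
  for (ty in c("direct", "indirect", "total")) for (tr in traits) {
    sel <- out$effect_type == ty & out$trait == tr & !is.na(out$p)
    if (any(sel)) out$q[sel] <- bh_fdr(out$p[sel])$q
  }
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values plus the -log10(p) cutoff corresponding to the largest
#' p-value rejected at the requested FDR level (the conventional way a
#' genome-wide significance line is reported).
#'
#' @param pvalues numeric p-values in (0, 1].
#' @param fdr FDR level for the reported threshold (default 0.05).
#' @return list with `q` (q-values), `n_rejected`, and
#'   `threshold_neglog10p` (NA when nothing is rejected).
#' @export
bh_fdr <- function(pvalues, fdr = 0.05) {
  stopifnot(all(pvalues > 0 & pvalues <= 1, na.rm = TRUE))
  q <- p.adjust(pvalues, method = "BH")
  rej <- which(q <= fdr)
  list(q = q,
       n_rejected = length(rej),
       threshold_neglog10p = if (length(rej) > 0L)
         -log10(max(pvalues[rej])) else NA_real_)
}
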