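# Multi-trait mixed model: REML fit, per-SNP scan, model-fit statistics.

# Align phenotypes and kinship on shared samples and drop incomplete rows.
.prepare_mtm_data <- function(pheno, K) {
  pheno <- as.data.frame(pheno)
  ids <- .match_samples(rownames(pheno), rownames(K),
                        c("phenotypes", "kinship"))
  Y <- as.matrix(pheno[ids, , drop = FALSE])
  cc <- complete.cases(Y)
  if (!all(cc)) {
    message("listwise deletion of ", sum(!cc),
            " sample(s) with missing phenotypes")
    ids <- ids[cc]
    Y <- Y[cc, , drop = FALSE]
  }
  list(Y = Y, K = kinship_subset(K, ids), ids = ids)
}

#' Fit the multi-trait animal model by REML
#'
#' Model: Y = 1 mu' + g + e with vec(g) ~ N(0, Sigma_g (x) K) and
#' vec(e) ~ N(0, Sigma_e (x) I). Estimation works on REML contrasts after
#' an eigendecomposition of the projected kinship matrix: EM updates (whose
#' restricted likelihood is non-decreasing) followed by a quasi-Newton
#' polish on the log-Cholesky scale.
#'
#' @param pheno data.frame of traits (rownames = sample ids); rows with any
#'   missing trait are dropped.
#' @param K a `kinship_matrix` covering the samples.
#' @param maxit,tol EM iteration cap and relative logL convergence
#'   tolerance.
#' @param init optional list with starting matrices `sigma_g`, `sigma_e`.
#' @return A `mtm_fit` with `sigma_g`, `sigma_e`, restricted `logL`,
#'   parameter count `k = t(t+1)` (both covariance matrices), the EM logL
#'   `trace`, and bookkeeping fields.
#' @export
fit_mtm_reml <- function(pheno, K, maxit = 1000L, tol = 1e-10, init = NULL) {
  dat <- .prepare_mtm_data(pheno, K)
  t <- ncol(dat$Y)
  ct <- .contrast_transform(dat$Y, dat$K)
  em <- .em_2comp(ct$Z, ct$d,
                  Sg0 = init$sigma_g, Se0 = init$sigma_e,
                  maxit = maxit, tol = tol)
  pol <- .polish_2comp(ct$Z, ct$d, em$sigma_g, em$sigma_e)
  if (!is.finite(pol$logL))
    .stopf("REML did not converge; last EM logL %.6f", em$logL)
  structure(list(
    sigma_g = pol$sigma_g, sigma_e = pol$sigma_e,
    logL = pol$logL, k = t * (t + 1L),
    n_records = nrow(dat$Y), traits = colnames(dat$Y),
    trace = em$trace, kinship_kind = attr(dat$K, "kind"),
    samples = dat$ids,
    fingerprint = .data_fingerprint(dat$Y)
  ), class = c("mtm_fit", "mixed_model_fit"))
}

#' @export
print.mtm_fit <- function(x, ...) {
  cat("Multi-trait mixed model (REML), traits:",
      paste(x$traits, collapse = ", "), "\n")
  cat(sprintf("  n = %d, logL = %.4f, k = %d\n", x$n_records, x$logL, x$k))
  cat("  genetic covariance:\n")
  print(round(x$sigma_g, 4))
  cat("  residual covariance:\n")
  print(round(x$sigma_e, 4))
  invisible(x)
}

#' Information criteria on the half-negative scale
#'
#' AIC = -2 logL + 2k and BIC = -2 logL + k log(n), reported as
#' -AIC/2 = logL - k and -BIC/2 = logL - (k/2) log(n) so that larger is
#' better and the values sit on the logL scale.
#'
#' @param fit a `mtm_fit` or `sem_fit` (anything with `logL` and `k`).
#' @param n_records number of records used for the BIC; defaults to the
#'   fit's record count.
#' @param k optional override of the parameter count (e.g. to reproduce a
#'   fixed-k reporting convention).
#' @return named numeric vector `logL`, `half_neg_aic`, `half_neg_bic`.
#' @export
model_fit_stats <- function(fit, n_records = fit$n_records, k = fit$k) {
  stopifnot(k >= 1, n_records > 0)
  c(logL = fit$logL,
    half_neg_aic = fit$logL - k,
    half_neg_bic = fit$logL - (k / 2) * log(n_records))
}

#' Compare fitted models
#'
#' One row per fit with logL, -AIC/2 and -BIC/2; no winner is declared.
#' Fits must come from the same data (checked via a data fingerprint).
#'
#' @param fits named list of fits.
#' @param n_records record count for the BIC term (defaults to the first
#'   fit's).
#' @param k optional vector of parameter-count overrides (recycled).
#' @return data.frame with columns model, logL, k, half_neg_aic,
#'   half_neg_bic.
#' @export
compare_models <- function(fits, n_records = NULL, k = NULL) {
  stopifnot(length(fits) >= 1L)
  fps <- vapply(fits, function(f) f$fingerprint, character(1))
  if (length(unique(fps)) > 1L)
    .stopf("fits were produced from different data (fingerprint mismatch)")
  if (is.null(n_records)) n_records <- fits[[1L]]$n_records
  if (is.null(k)) k <- vapply(fits, function(f) f$k, numeric(1))
  k <- rep_len(k, length(fits))
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("model", seq_along(fits))
  rows <- lapply(seq_along(fits), function(i)
    model_fit_stats(fits[[i]], n_records, k[i]))
  data.frame(model = nm,
             logL = vapply(rows, `[[`, numeric(1), "logL"),
             k = k,
             half_neg_aic = vapply(rows, `[[`, numeric(1), "half_neg_aic"),
             half_neg_bic = vapply(rows, `[[`, numeric(1), "half_neg_bic"),
             row.names = NULL)
}

# Shared per-SNP generalized least squares scan. Given component matrices
# (A, C) of the marginal covariance d_i A + C, regress the rotated
# phenotypes on (intercept, SNP dosage) per diagonalized component and map
# estimates back. Returns the t x p estimate matrix, elementwise variances,
# and the per-SNP transform needed for full covariance recovery.
.gls_scan <- function(Y, Wimp, eig, A, C) {
  n <- nrow(Y); t <- ncol(Y); p <- ncol(Wimp)
  ge <- .geigen(A, C)
  U <- eig$vectors; d <- eig$values
  Zs <- crossprod(U, Y) %*% ge$R              # n x t rotated responses
  cvec <- as.numeric(crossprod(U, rep(1, n)))
  Wt <- crossprod(U, Wimp)                    # n x p rotated dosages
  Gamma <- matrix(NA_real_, p, t)
  Vgam <- matrix(NA_real_, p, t)
  for (k in seq_len(t)) {
    u <- 1 / (1 + d * ge$theta[k])
    a11 <- sum(u * cvec^2)
    a12 <- colSums(Wt * (u * cvec))
    a22 <- colSums(Wt^2 * u)
    b1 <- sum(u * cvec * Zs[, k])
    b2 <- colSums(Wt * (u * Zs[, k]))
    det <- a11 * a22 - a12^2
    ok <- det > 1e-10 * a11 * pmax(a22, 1e-300)
    Gamma[ok, k] <- (a11 * b2[ok] - a12[ok] * b1) / det[ok]
    Vgam[ok, k] <- a11 / det[ok]
  }
  Rinv <- solve(ge$R)
  # s' = gamma' R^-1, Var(s_t) = sum_k Vgam_k (R^-1[k, t])^2
  list(est = Gamma %*% Rinv, var = Vgam %*% Rinv^2,
       Rinv = Rinv, Vgam = Vgam)
}

.scan_result <- function(g, est, varmat, traits) {
  p <- nrow(est)
  se <- sqrt(varmat)
  tval <- est / se
  pval <- 2 * pnorm(-abs(tval))
  out <- data.frame(
    snp = rep(g$map$id, times = length(traits)),
    chrom = rep(g$map$chrom, times = length(traits)),
    pos = rep(g$map$pos, times = length(traits)),
    trait = rep(traits, each = p),
    estimate = as.numeric(est),
    se = as.numeric(se),
    t = as.numeric(tval),
    p = as.numeric(pval),
    row.names = NULL
  )
  class(out) <- c("snp_scan", "data.frame")
  out
}

#' Per-SNP multi-trait association scan
#'
#' Each SNP is entered separately as a fixed covariate (one allele
#' substitution effect per trait) in the multi-trait model, with variance
#' components held fixed at the no-SNP estimates (scan strategy with fixed
#' components). Estimates and standard errors come from the mixed-model
#' normal equations; T = estimate / se with two-sided p-values from the
#' standard normal reference.
#'
#' SNPs with zero dosage variance are reported with missing estimates
#' rather than raising an error.
#'
#' @param pheno data.frame of traits.
#' @param g a `genotype_matrix` (missing dosages are mean-imputed).
#' @param K a `kinship_matrix`.
#' @param vc a `mtm_fit` (or list with `sigma_g`, `sigma_e`) estimated on
#'   the no-SNP model.
#' @return data.frame of class `snp_scan` with columns snp, chrom, pos,
#'   trait, estimate, se, t, p.
#' @export
mtm_snp_scan <- function(pheno, g, K, vc) {
  dat <- .prepare_mtm_data(pheno, K)
  g <- impute_dosages(g)
  if (!all(dat$ids %in% rownames(g$dosages)))
    .stopf("genotypes missing for some phenotyped samples")
  W <- g$dosages[dat$ids, , drop = FALSE]
  eig <- K_eigen(dat$K)
  res <- .gls_scan(dat$Y, W, eig, vc$sigma_g, vc$sigma_e)
  mono <- apply(W, 2L, function(x) var(x) == 0)
  res$est[mono, ] <- NA_real_
  res$var[mono, ] <- NA_real_
  .scan_result(g, res$est, res$var, colnames(dat$Y))
}

#' Write a SNP scan as TSV
#' @param scan a `snp_scan` data.frame.
#' @param path output path.
#' @export
write_scan <- function(scan, path) {
  data.table::fwrite(as.data.frame(scan), path, sep = "\t", na = "NA")
  invisible(path)
}
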