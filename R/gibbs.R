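# Gibbs sampling of the multi-trait animal model: posterior draws of the
# genetic and residual covariance matrices, used by the network search.

# Inverse-Wishart draw via the Wishart of the inverse scale.
.riwish <- function(df, S) {
  W <- rWishart(1L, df, chol2inv(chol(.sym(S))))[, , 1L]
  chol2inv(chol(.sym(W)))
}

#' Gibbs sampler for the multi-trait animal model
#'
#' Samples location parameters and both covariance matrices from their full
#' conditionals: trait means and (rotated) polygenic effects from normals,
#' Sigma_g and Sigma_e from inverse-Wishart conditionals. The kinship
#' matrix is eigendecomposed once so every update is a vectorized
#' operation on independent components.
#'
#' Priors are inverse-Wishart on both covariance matrices, by default
#' weakly informative with df = t + 2 and scale 0.5 I.
#'
#' @param pheno data.frame of traits.
#' @param K a `kinship_matrix` (use [precompute_kinship_eigen()] when
#'   calling repeatedly with the same K).
#' @param iterations,burn_in,thin chain settings; stored draws number
#'   `(iterations - burn_in) / thin`.
#' @param seed integer seed; the whole chain is reproducible from it.
#' @param priors list with `df` and `scale` (t x t PD matrix or scalar
#'   multiple of I) shared by both components.
#' @return A `posterior_draws` object: arrays `sigma_g`, `sigma_e`
#'   (S x t x t) and chain metadata.
#' @export
fit_mtm_gibbs <- function(pheno, K, iterations = 10000L, burn_in = 2000L,
                          thin = 10L, seed = 20181009L, priors = NULL) {
  stopifnot(iterations > 0L, thin > 0L, burn_in >= 0L,
            burn_in < iterations)
  dat <- .prepare_mtm_data(pheno, K)
  Y <- dat$Y
  n <- nrow(Y); t <- ncol(Y)
  nu0 <- if (is.null(priors$df)) t + 2 else priors$df
  S0 <- if (is.null(priors$scale)) diag(0.5, t) else priors$scale
  if (is.numeric(S0) && length(S0) == 1L) S0 <- diag(S0, t)
  S0 <- .sym(as.matrix(S0))
  if (min(eigen(S0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    .stopf("prior scale matrix must be positive definite")
  if (nu0 <= t - 1) .stopf("prior df must exceed t - 1")

  eig <- K_eigen(dat$K)
  U <- eig$vectors
  d <- eig$values
  pos <- d > 1e-8
  n_pos <- sum(pos)
  Ystar <- crossprod(U, Y)
  cvec <- as.numeric(crossprod(U, rep(1, n)))
  sc2 <- sum(cvec^2)

  set.seed(seed)
  S_emp <- cov(Y)
  Sg <- .sym(S_emp / 2); Se <- .sym(S_emp / 2)
  mu <- colMeans(Y)
  gstar <- matrix(0, n, t)

  n_store <- (iterations - burn_in) %/% thin
  draws_g <- array(NA_real_, c(n_store, t, t))
  draws_e <- array(NA_real_, c(n_store, t, t))
  stored <- 0L

  for (it in seq_len(iterations)) {
    ge <- .geigen(Sg, Se)
    Rinv <- solve(ge$R)
    resid <- Ystar - tcrossprod(cvec, rep(1, t)) * rep(mu, each = n)
    Zres <- resid %*% ge$R
    vmat <- outer(d, ge$theta)
    postv <- vmat / (1 + vmat)
    gtil <- postv * Zres + sqrt(postv) * matrix(rnorm(n * t), n, t)
    gstar <- gtil %*% Rinv

    SSg <- crossprod(gstar[pos, , drop = FALSE] / sqrt(d[pos]))
    Sg <- .riwish(nu0 + n_pos, S0 + SSg)
    E <- resid - gstar
    Se <- .riwish(nu0 + n, S0 + crossprod(E))

    mhat <- as.numeric(crossprod(Ystar - gstar, cvec)) / sc2
    mu <- mhat + as.numeric(t(chol(Se)) %*% rnorm(t)) / sqrt(sc2)

    if (it > burn_in && (it - burn_in) %% thin == 0L) {
      stored <- stored + 1L
      draws_g[stored, , ] <- Sg
      draws_e[stored, , ] <- Se
    }
  }
  structure(list(
    sigma_g = draws_g, sigma_e = draws_e,
    traits = colnames(Y),
    iterations = iterations, burn_in = burn_in, thin = thin, seed = seed,
    n_stored = n_store,
    priors = list(df = nu0, scale = S0),
    kinship_kind = attr(dat$K, "kind"),
    fingerprint = .data_fingerprint(Y)
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", x$n_stored, "stored draws over",
      length(x$traits), "traits\n")
  cat(sprintf("  chain: %d iterations, burn-in %d, thinning %d, seed %d\n",
              x$iterations, x$burn_in, x$thin, x$seed))
  pm <- apply(x$sigma_g, c(2, 3), mean)
  cat("  posterior mean genetic covariance:\n")
  print(round(pm, 4))
  invisible(x)
}

# Spectral density of a series at frequency zero, via an AR fit
# (order chosen by AIC), for Markov-chain standard errors.
.spectrum0 <- function(x) {
  x <- as.numeric(x)
  if (var(x) == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(20L, length(x) %/% 4L)),
                  error = function(e) NULL)
  if (is.null(fit)) return(var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the mean of the first `frac1` fraction of a chain with
#' the mean of the last `frac2` fraction, with spectral-density standard
#' errors. |z| above ~3 flags non-convergence.
#'
#' @param x numeric vector of draws (one logged scalar component).
#' @param frac1,frac2 fractions of the chain to compare.
#' @return z statistic.
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2L, floor(frac1 * n)))]
  b <- x[(n - max(2L, floor(frac2 * n)) + 1L):n]
  v <- .spectrum0(a) / length(a) + .spectrum0(b) / length(b)
  if (v <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(v)
}
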