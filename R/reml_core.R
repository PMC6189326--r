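# Core machinery for the two-variance-component multivariate model
#
#   vec(Y) ~ N(vec(1 mu'), Sg (x) K + Se (x) I)
#
# All fits work on REML contrasts: with Q an orthonormal basis of the
# orthogonal complement of the intercept, the rotated data Z = U' Q' Y
# (U from the eigendecomposition of Q' K Q) has independent rows
# z_i ~ N(0, d_i Sg + Se). Likelihood evaluations then reduce to the
# simultaneous diagonalization of (Sg, Se): with Se = L L' and
# L^-1 Sg L^-T = P Theta P', the matrix R = L^-T P satisfies R' Se R = I
# and R' Sg R = Theta, so V_i^-1 = R (I + d_i Theta)^-1 R'.

# Eigendecomposition of K, cached on the matrix via an attribute so scans
# and fits can share it.
K_eigen <- function(K) {
  cached <- attr(K, "eigen")
  if (!is.null(cached)) return(cached)
  Km <- unclass(K)
  attributes(Km) <- list(dim = dim(Km))
  if (all(Km[row(Km) != col(Km)] == 0)) {
    e <- list(values = diag(Km), vectors = diag(nrow(Km)))
  } else {
    e <- eigen(.sym(Km), symmetric = TRUE)
  }
  e$values[e$values < 0] <- 0
  e
}

#' Attach a precomputed eigendecomposition to a kinship matrix
#'
#' Fitting, sampling and scanning all need the eigendecomposition of K;
#' for large n it pays to compute it once and reuse it.
#'
#' @param K a `kinship_matrix`.
#' @return The same matrix with the decomposition cached in an attribute.
#' @export
precompute_kinship_eigen <- function(K) {
  attr(K, "eigen") <- K_eigen(K)
  K
}

# REML contrast transform: returns rotated zero-mean data Z ((n-1) x t)
# and eigenvalues d of the projected kinship.
.contrast_transform <- function(Y, K) {
  n <- nrow(Y)
  Q <- qr.Q(qr(matrix(1, n, 1)), complete = TRUE)[, -1L, drop = FALSE]
  Kt <- crossprod(Q, unclass(K) %*% Q)
  e <- eigen(.sym(Kt), symmetric = TRUE)
  d <- pmax(e$values, 0)
  Z <- crossprod(e$vectors, crossprod(Q, as.matrix(Y)))
  list(Z = Z, d = d)
}

# Simultaneous diagonalization of (Sg, Se); Se must be PD.
.geigen <- function(Sg, Se) {
  t <- ncol(Se)
  U <- tryCatch(chol(.sym(Se)),
                error = function(e) chol(.sym(Se) + diag(1e-8, t)))
  L <- t(U)
  M <- forwardsolve(L, t(forwardsolve(L, .sym(Sg))))
  e <- eigen(.sym(M), symmetric = TRUE)
  R <- backsolve(U, e$vectors)
  list(R = R, theta = pmax(e$values, 0),
       logdet_se = 2 * sum(log(diag(U))))
}

# Restricted log-likelihood of (Sg, Se) for rotated contrast data.
.loglik2 <- function(Sg, Se, d, Z) {
  ge <- tryCatch(.geigen(Sg, Se), error = function(e) NULL)
  if (is.null(ge)) return(-Inf)
  Zt <- Z %*% ge$R
  lam <- 1 + outer(d, ge$theta)                      # n x t
  n <- nrow(Z); t <- ncol(Z)
  -0.5 * (n * t * log(2 * pi) + n * ge$logdet_se + sum(log(lam)) +
          sum(Zt^2 / lam))
}

# EM-REML for (Sg, Se); monotone in the restricted likelihood. Returns the
# estimates plus the logL trace.
.em_2comp <- function(Z, d, Sg0 = NULL, Se0 = NULL,
                      maxit = 500L, tol = 1e-8) {
  n <- nrow(Z); t <- ncol(Z)
  S_emp <- crossprod(Z) / n
  if (is.null(Sg0)) Sg0 <- S_emp / 2 + diag(1e-6, t)
  if (is.null(Se0)) Se0 <- S_emp / 2 + diag(1e-6, t)
  Sg <- Sg0; Se <- Se0
  pos <- d > 1e-10
  n_pos <- sum(pos)
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    ge <- .geigen(Sg, Se)
    Zt <- Z %*% ge$R
    lam <- 1 + outer(d, ge$theta)
    ll <- -0.5 * (n * t * log(2 * pi) + n * ge$logdet_se +
                  sum(log(lam)) + sum(Zt^2 / lam))
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) <
        tol * (abs(trace[it - 1L]) + 1e-10)) break
    vmat <- outer(d, ge$theta)            # prior variances of g-tilde
    postv <- vmat / lam                   # posterior variances
    M <- postv * Zt                       # posterior means
    Rinv <- solve(ge$R)                   # R^-1; note g = R'^-1 g~, e = R'^-1 e~
    Mg <- M[pos, , drop = FALSE] / sqrt(d[pos])
    Sg_t <- crossprod(Mg) + diag(colSums(postv[pos, , drop = FALSE] /
                                           d[pos]), t)
    Se_t <- crossprod(Zt - M) + diag(colSums(postv), t)
    Sg <- .sym(crossprod(Rinv, Sg_t %*% Rinv)) / max(n_pos, 1L)
    Se <- .sym(crossprod(Rinv, Se_t %*% Rinv)) / n
  }
  list(sigma_g = Sg, sigma_e = Se, logL = trace[length(trace)], trace = trace)
}

# Quasi-Newton polish of the EM solution on the log-Cholesky scale, so EM
# handles the global structure and BFGS the final digits.
.polish_2comp <- function(Z, d, Sg, Se) {
  t <- ncol(Z)
  np <- .logchol_npar(t)
  par0 <- c(.logchol_pack(Sg + diag(1e-10, t)),
            .logchol_pack(Se + diag(1e-10, t)))
  negll <- function(par) {
    Sg_ <- .logchol_unpack(par[seq_len(np)], t)
    Se_ <- .logchol_unpack(par[np + seq_len(np)], t)
    ll <- .loglik2(Sg_, Se_, d, Z)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  opt <- optim(par0, negll, method = "L-BFGS-B",
               lower = rep(-20, 2 * np), upper = rep(20, 2 * np),
               control = list(maxit = 400L, factr = 1e3))
  list(sigma_g = .logchol_unpack(opt$par[seq_len(np)], t),
       sigma_e = .logchol_unpack(opt$par[np + seq_len(np)], t),
       logL = -opt$value, convergence = opt$convergence)
}
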