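# Internal helpers shared across modules.

.sym <- function(S) (S + t(S)) / 2

# Pack a symmetric positive-definite matrix as log-Cholesky parameters
# (log of the diagonal, raw off-diagonals of the lower factor).
.logchol_pack <- function(S) {
  L <- t(chol(.sym(S)))
  p <- ncol(S)
  out <- numeric(0)
  for (j in seq_len(p)) {
    out <- c(out, log(L[j, j]), if (j < p) L[(j + 1):p, j])
  }
  out
}

.logchol_unpack <- function(par, p) {
  L <- matrix(0, p, p)
  idx <- 1L
  for (j in seq_len(p)) {
    L[j, j] <- exp(par[idx])
    idx <- idx + 1L
    if (j < p) {
      L[(j + 1):p, j] <- par[idx:(idx + p - j - 1L)]
      idx <- idx + p - j
    }
  }
  tcrossprod(L)
}

.logchol_npar <- function(p) p * (p + 1L) / 2L

# Cheap data fingerprint so model-comparison tables can refuse fits from
# different data sets without hauling the data around.
.data_fingerprint <- function(Y) {
  Y <- as.matrix(Y)
  sprintf("%dx%d|%.10g|%.10g", nrow(Y), ncol(Y),
          sum(Y, na.rm = TRUE), sum(Y^2, na.rm = TRUE))
}

# Align two sample-indexed objects by identifier; drops unmatched samples
# with a message (order of the first argument wins).
.match_samples <- function(ids_a, ids_b, what = c("phenotypes", "genotypes")) {
  common <- intersect(ids_a, ids_b)
  n_drop <- (length(ids_a) - length(common)) + (length(ids_b) - length(common))
  if (length(common) == 0L)
    stop("no overlapping sample identifiers between ", what[1L], " and ", what[2L])
  if (n_drop > 0L)
    message("dropping ", n_drop, " unmatched sample(s) when aligning ",
            what[1L], " and ", what[2L])
  common
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
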