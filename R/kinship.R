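# Relationship matrices: marker-based (VanRaden G) and pedigree-based (A).

#' Construct a kinship matrix object
#'
#' @param values n x n symmetric relationship matrix with sample ids as
#'   dimnames.
#' @param kind `"genomic_G"` or `"pedigree_A"`.
#' @param check_psd verify positive semi-definiteness (eigenvalue floor
#'   -1e-8) and repair by a diagonal jitter if violated. Can be disabled
#'   when PSD is guaranteed by construction (e.g. principal submatrices).
#' @return matrix of class `kinship_matrix` with a `kind` attribute.
#' @export
kinship_matrix <- function(values, kind = c("genomic_G", "pedigree_A"),
                           check_psd = TRUE) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) .stopf("kinship matrix must be square")
  if (max(abs(values - t(values))) > 1e-10)
    .stopf("kinship matrix is not symmetric")
  values <- .sym(values)
  if (check_psd) {
    ev_min <- min(eigen(values, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
      jit <- abs(ev_min) + 1e-8
      message(sprintf("kinship not PSD (min eigenvalue %.3g); adding %.3g to diagonal",
                      ev_min, jit))
      diag(values) <- diag(values) + jit
    }
  }
  structure(values, kind = kind, class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", attr(x, "kind"), "): ", nrow(x), " x ", ncol(x),
      ", mean diagonal ", sprintf("%.4f", mean(diag(x))), "\n", sep = "")
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' G = M M' / (2 sum p_j q_j), where M holds dosages centered by twice the
#' observed allele frequency per SNP and q_j = 1 - p_j. Monomorphic SNPs
#' contribute zero to both the numerator and the denominator sum.
#'
#' @param g a `genotype_matrix` with no missing dosages (mean-impute first;
#'   see [impute_dosages()]).
#' @return A `kinship_matrix` of kind `"genomic_G"`.
#' @export
grm_vanraden <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  dos <- g$dosages
  if (anyNA(dos)) .stopf("missing dosages present; run impute_dosages() first")
  if (nrow(dos) < 2L || ncol(dos) < 1L)
    .stopf("need at least 2 samples and 1 SNP")
  p_hat <- colMeans(dos) / 2
  poly <- p_hat > 0 & p_hat < 1
  denom <- 2 * sum(p_hat[poly] * (1 - p_hat[poly]))
  if (denom == 0) .stopf("degenerate input: all SNPs monomorphic")
  M <- sweep(dos[, poly, drop = FALSE], 2L, 2 * p_hat[poly], "-")
  G <- tcrossprod(M) / denom
  dimnames(G) <- list(rownames(dos), rownames(dos))
  kinship_matrix(G, "genomic_G")
}

# Topologically sort a pedigree (parents before offspring); errors on a
# cycle, naming the individuals involved.
.ped_sort <- function(ped) {
  ids <- ped$id
  if (anyDuplicated(ids)) .stopf("duplicated individuals in pedigree")
  known <- function(x) ifelse(x %in% ids, x, "0")
  sire <- known(ped$sire); dam <- known(ped$dam)
  placed <- character(0)
  remaining <- seq_along(ids)
  order_idx <- integer(0)
  while (length(remaining) > 0L) {
    ready <- remaining[(sire[remaining] %in% c("0", placed)) &
                       (dam[remaining] %in% c("0", placed))]
    if (length(ready) == 0L)
      .stopf("cyclic pedigree involving: %s",
             paste(ids[remaining], collapse = ", "))
    order_idx <- c(order_idx, ready)
    placed <- c(placed, ids[ready])
    remaining <- setdiff(remaining, ready)
  }
  ped[order_idx, , drop = FALSE]
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular method: founders have diagonal 1; for individual i with parents
#' s and d, A(i, j) = (A(j, s) + A(j, d)) / 2 for earlier j, and
#' A(i, i) = 1 + A(s, d) / 2. An unknown parent (coded `"0"`) contributes
#' zero relationship.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (see
#'   [read_pedigree()]).
#' @return A `kinship_matrix` of kind `"pedigree_A"` over all pedigree
#'   individuals, in pedigree (topologically sorted) order.
#' @export
nrm_from_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  ped$id <- as.character(ped$id)
  ped$sire <- as.character(ped$sire)
  ped$dam <- as.character(ped$dam)
  ped <- .ped_sort(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  pos <- setNames(seq_len(n), ped$id)
  si <- ifelse(ped$sire %in% ped$id, pos[ped$sire], 0L)
  di <- ifelse(ped$dam %in% ped$id, pos[ped$dam], 0L)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + (if (s > 0L && d > 0L) 0.5 * A[s, d] else 0)
  }
  kinship_matrix(A, "pedigree_A")
}

#' Subset a kinship matrix to a set of samples
#' @param K a `kinship_matrix`.
#' @param samples character vector of sample ids (all must be present).
#' @export
kinship_subset <- function(K, samples) {
  miss <- setdiff(samples, rownames(K))
  if (length(miss) > 0L)
    .stopf("samples absent from kinship matrix: %s",
           paste(head(miss, 5L), collapse = ", "))
  kinship_matrix(K[samples, samples, drop = FALSE], attr(K, "kind"),
                 check_psd = FALSE)
}

#' Write / read a kinship matrix as TSV
#'
#' Header row and first column carry sample ids.
#' @param K a `kinship_matrix`.
#' @param path file path.
#' @export
write_kinship <- function(K, path) {
  df <- data.frame(sample_id = rownames(K), as.data.frame(unclass(K)),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_kinship
#' @param kind kinship kind for the object read back.
#' @export
read_kinship <- function(path, kind = c("genomic_G", "pedigree_A")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(m) <- as.character(dt[[1L]])
  kinship_matrix(m, kind)
}
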