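# Genotype/phenotype/pedigree input-output and marker quality control.

#' Construct a genotype matrix object
#'
#' Container for additive-coded dosages (counts of the A allele, 0/1/2, NA
#' allowed) together with the SNP map. Rows are samples, columns are SNPs.
#'
#' @param dosages numeric matrix, n samples x p SNPs, values in {0, 1, 2, NA}.
#' @param map data.frame with one row per SNP; columns `id`, `chrom`, `pos`,
#'   `allele_a`, `allele_b`. Missing columns are filled with placeholders.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, map = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(dosages)), arr.ind = TRUE)[1L, ]
    .stopf("dosage outside {0,1,2} at row '%s', column '%s'",
           rownames(dosages)[w[1L]], colnames(dosages)[w[2L]])
  }
  if (is.null(map)) {
    map <- data.frame(id = colnames(dosages), chrom = NA_character_,
                      pos = NA_integer_, allele_a = "A", allele_b = "B",
                      stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map)
  for (col in c("chrom", "pos", "allele_a", "allele_b"))
    if (is.null(map[[col]])) map[[col]] <- NA
  if (anyDuplicated(map$id)) .stopf("duplicated SNP identifiers in map")
  if (nrow(map) != ncol(dosages))
    .stopf("map has %d rows but dosage matrix has %d columns",
           nrow(map), ncol(dosages))
  structure(list(dosages = dosages, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "SNPs\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from disk
#'
#' Supports two text dialects: a plain additive TSV (header row of SNP ids,
#' first column of sample ids, cells 0/1/2) and the PLINK `.raw` additive
#' recoding (six leading columns FID/IID/PAT/MAT/SEX/PHENOTYPE, SNP headers
#' of the form `id_allele`).
#'
#' Unparseable cells become missing dosages. Out-of-range numeric dosages
#' raise an error naming the offending row and column.
#'
#' @param path file path.
#' @param dialect `"additive-tsv"` or `"plink-raw"`.
#' @param map optional SNP map data.frame (see [genotype_matrix()]).
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, dialect = c("additive-tsv", "plink-raw"),
                           map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("genotype file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", "", "."))
  if (ncol(dt) < 2L) .stopf("malformed genotype header in %s", path)
  if (dialect == "plink-raw") {
    lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(lead %in% names(dt)[seq_len(6L)]))
      .stopf("malformed PLINK .raw header: expected leading columns %s",
             paste(lead, collapse = " "))
    samples <- as.character(dt$IID)
    block <- dt[, -(1:6), drop = FALSE]
    # header "snp1_A" -> SNP id "snp1", counted allele "A"
    ids <- sub("_[^_]*$", "", names(block))
    counted <- sub("^.*_", "", names(block))
    dos <- as.matrix(block)
    dimnames(dos) <- list(samples, ids)
    if (is.null(map))
      map <- data.frame(id = ids, chrom = NA_character_, pos = NA_integer_,
                        allele_a = counted, allele_b = NA_character_,
                        stringsAsFactors = FALSE)
  } else {
    samples <- as.character(dt[[1L]])
    dos <- as.matrix(dt[, -1L, drop = FALSE])
    suppressWarnings(storage.mode(dos) <- "double")
    dimnames(dos) <- list(samples, names(dt)[-1L])
  }
  suppressWarnings(storage.mode(dos) <- "double")
  g <- genotype_matrix(dos, map)
  message("read ", nrow(g$dosages), " samples x ", ncol(g$dosages),
          " SNPs from ", path)
  g
}

#' Write genotypes to disk
#'
#' Emits the same dialects [read_genotypes()] parses, so that a write/read
#' cycle is lossless.
#'
#' @inheritParams read_genotypes
#' @param g a `genotype_matrix`.
#' @export
write_genotypes <- function(g, path, dialect = c("additive-tsv", "plink-raw")) {
  dialect <- match.arg(dialect)
  dos <- g$dosages
  if (dialect == "plink-raw") {
    counted <- ifelse(is.na(g$map$allele_a), "A", g$map$allele_a)
    out <- data.frame(FID = rownames(dos), IID = rownames(dos),
                      PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9,
                      check.names = FALSE)
    block <- as.data.frame(dos)
    names(block) <- paste0(g$map$id, "_", counted)
    out <- cbind(out, block)
    data.table::fwrite(out, path, sep = " ", na = "NA", quote = FALSE)
  } else {
    out <- data.frame(sample_id = rownames(dos), dos, check.names = FALSE)
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' Read a phenotype (or covariate) table
#'
#' TSV with a header; first column holds sample identifiers, remaining
#' columns are traits (or covariates).
#'
#' @param path file path.
#' @return data.frame with rownames set to sample ids.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  rownames(dt) <- as.character(dt[[1L]])
  dt[[1L]] <- NULL
  dt
}

#' Read a pedigree table
#'
#' TSV with columns `id`, `sire`, `dam`; `0` (or NA) encodes an unknown
#' parent.
#'
#' @param path file path.
#' @return data.frame with character columns id/sire/dam.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) .stopf("pedigree file not found: %s", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          colClasses = "character")
  names(dt)[1:3] <- c("id", "sire", "dam")
  dt$sire[is.na(dt$sire)] <- "0"
  dt$dam[is.na(dt$dam)] <- "0"
  dt
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts against
#' Hardy-Weinberg proportions at the sample allele frequency. No continuity
#' correction. A monomorphic SNP returns `chi2 = 0`, `p = 1`.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return list with `chi2` and `p`.
#' @export
#' @examples
#' hwe_chisq(25, 50, 25)  # exact HWE proportions -> p = 1
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) .stopf("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) .stopf("undefined input: total genotype count is zero")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Marker quality control
#'
#' Removes SNPs with minor allele frequency below `maf_min`, call rate below
#' `call_rate_min`, or Hardy-Weinberg chi-square p-value below `hwe_p_min`.
#' Allele frequencies and call rates are computed on observed (non-missing)
#' calls. A SNP is attributed to the first filter it fails, in the fixed
#' order MAF, call rate, HWE, so report counts are deterministic.
#'
#' @param g a `genotype_matrix`.
#' @param maf_min,call_rate_min,hwe_p_min thresholds in \[0, 1\].
#' @return list with the filtered `genotype_matrix` and a `qc_report`
#'   (counts removed per filter plus retained count).
#' @export
apply_qc <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                     hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  thr <- c(maf_min, call_rate_min, hwe_p_min)
  if (any(thr < 0 | thr > 1)) .stopf("QC thresholds must lie in [0, 1]")
  dos <- g$dosages
  n_obs <- colSums(!is.na(dos))
  call_rate <- n_obs / nrow(dos)
  p_hat <- colMeans(dos, na.rm = TRUE) / 2
  p_hat[n_obs == 0L] <- NA
  maf <- pmin(p_hat, 1 - p_hat)
  n_AA <- colSums(dos == 2, na.rm = TRUE)
  n_Aa <- colSums(dos == 1, na.rm = TRUE)
  n_aa <- colSums(dos == 0, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    if (n_obs[j] == 0L) return(1)
    hwe_chisq(n_AA[j], n_Aa[j], n_aa[j])$p
  }, numeric(1))

  fail_maf <- is.na(maf) | maf < maf_min
  fail_cr <- call_rate < call_rate_min
  fail_hwe <- hwe_p < hwe_p_min
  first_fail <- rep("retained", ncol(dos))
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_cr] <- "call_rate"
  first_fail[fail_maf] <- "maf"

  keep <- first_fail == "retained"
  report <- structure(list(
    input = ncol(dos),
    removed_maf = sum(first_fail == "maf"),
    removed_call_rate = sum(first_fail == "call_rate"),
    removed_hwe = sum(first_fail == "hwe"),
    retained = sum(keep),
    thresholds = list(maf_min = maf_min, call_rate_min = call_rate_min,
                      hwe_p_min = hwe_p_min)
  ), class = "qc_report")
  if (!any(keep)) warning("all SNPs removed by QC; returning empty matrix")
  out <- genotype_matrix(dos[, keep, drop = FALSE],
                         g$map[keep, , drop = FALSE])
  message(sprintf("QC: %d input, %d removed (maf %d, call rate %d, hwe %d), %d retained",
                  report$input,
                  report$input - report$retained,
                  report$removed_maf, report$removed_call_rate,
                  report$removed_hwe, report$retained))
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:\n")
  cat("  input SNPs:        ", x$input, "\n")
  cat("  removed (MAF):     ", x$removed_maf, "\n")
  cat("  removed (call rate):", x$removed_call_rate, "\n")
  cat("  removed (HWE):     ", x$removed_hwe, "\n")
  cat("  retained:          ", x$retained, "\n")
  invisible(x)
}

#' Serialize a QC report as TSV
#' @param report a `qc_report`.
#' @param path output file path.
#' @export
write_qc_report <- function(report, path) {
  df <- data.frame(filter = c("maf", "call_rate", "hwe", "retained", "input"),
                   count = c(report$removed_maf, report$removed_call_rate,
                             report$removed_hwe, report$retained,
                             report$input))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Mean-impute missing dosages
#'
#' Replaces missing calls by the per-SNP mean dosage of observed calls.
#' Used before building relationship matrices or scanning, where a complete
#' matrix is required.
#'
#' @param g a `genotype_matrix`.
#' @return A `genotype_matrix` with no missing dosages (imputed values are
#'   fractional, which is intended).
#' @export
impute_dosages <- function(g) {
  dos <- g$dosages
  if (!anyNA(dos)) return(g)
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  dos[idx] <- mu[idx[, 2L]]
  out <- g
  out$dosages <- dos
  out
}

#' Pre-adjust phenotypes for nuisance covariates
#'
#' Per trait, replaces raw values by the residuals of an ordinary
#' least-squares fit on the supplied covariates (factors and/or continuous
#' variables). Aliased covariate columns are dropped by the fit with a
#' warning. With no covariates the table passes through unchanged.
#'
#' @param pheno data.frame of traits, rownames = sample ids.
#' @param covariates data.frame aligned to `pheno` rows (or NULL).
#' @param keep_mean if TRUE, the trait grand mean is added back to the
#'   residuals.
#' @return data.frame of adjusted phenotypes.
#' @export
preadjust_phenotypes <- function(pheno, covariates = NULL, keep_mean = FALSE) {
  pheno <- as.data.frame(pheno)
  if (is.null(covariates)) return(pheno)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(pheno))
    .stopf("covariate rows (%d) do not align to samples (%d)",
           nrow(covariates), nrow(pheno))
  out <- pheno
  for (tr in names(pheno)) {
    dat <- cbind(.y = pheno[[tr]], covariates)
    fit <- lm(.y ~ ., data = dat, na.action = stats::na.exclude)
    if (anyNA(coef(fit)))
      warning("rank-deficient covariate design for trait '", tr,
              "': aliased columns dropped")
    res <- residuals(fit)
    if (keep_mean) res <- res + mean(pheno[[tr]], na.rm = TRUE)
    out[[tr]] <- as.numeric(res)
  }
  out
}
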