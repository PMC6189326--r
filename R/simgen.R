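# Synthetic data with the statistical structure the method assumes:
# full-sib families (or unrelated founders), independent SNPs, polygenic
# effects with covariance Sigma_g (x) K, independent trait residuals, and
# QTL with direct effects on chosen traits, propagated through a recursive
# causal structure.

#' Simulation configuration
#'
#' Validates and assembles the generative-model settings. Phenotypes are
#' produced on the reduced form y = (I - Lambda)^-1 (W s + g + e), so
#' `lambda` is the ground-truth structural matrix in the order of
#' `traits`.
#'
#' @param n_individuals number of phenotyped individuals.
#' @param n_snps number of (independent) SNPs.
#' @param family_size full-sib family size; `n_individuals` must be a
#'   multiple. `family_size = 1` with `unrelated = TRUE` gives unrelated
#'   founders.
#' @param unrelated if TRUE individuals are unrelated founders (no
#'   pedigree structure beyond self).
#' @param maf_range founder minor-allele-frequency bounds (uniform draw).
#' @param traits trait names (defines t and the order of `lambda`).
#' @param lambda t x t strictly lower-triangular (in `traits` order)
#'   structural coefficient matrix.
#' @param sigma_g t x t PSD genetic covariance (structural scale).
#' @param psi length-t positive residual variances (structural scale).
#' @param qtl data.frame with columns `snp` (index), `trait` (index or
#'   name), `effect`: direct QTL effects.
#' @param seed integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_individuals = 1000L, n_snps = 500L,
                       family_size = 10L, unrelated = FALSE,
                       maf_range = c(0.05, 0.5),
                       traits = c("y1", "y2", "y3"),
                       lambda = matrix(0, length(traits), length(traits)),
                       sigma_g = diag(0.43, length(traits)),
                       psi = rep(1, length(traits)),
                       qtl = NULL, seed = 20181009L) {
  t <- length(traits)
  lambda <- as.matrix(lambda)
  stopifnot(nrow(lambda) == t, ncol(lambda) == t)
  if (any(lambda[upper.tri(lambda, diag = TRUE)] != 0))
    .stopf("lambda must be strictly lower-triangular in the trait order")
  sigma_g <- .sym(as.matrix(sigma_g))
  if (min(eigen(sigma_g, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    .stopf("sigma_g must be positive semi-definite")
  if (any(psi <= 0)) .stopf("psi must be positive")
  if (!unrelated && n_individuals %% family_size != 0L)
    .stopf("n_individuals (%d) is not a multiple of family_size (%d)",
           n_individuals, family_size)
  if (!is.null(qtl)) {
    qtl <- as.data.frame(qtl)
    if (is.character(qtl$trait)) qtl$trait <- match(qtl$trait, traits)
    stopifnot(all(qtl$snp >= 1), all(qtl$snp <= n_snps),
              all(qtl$trait >= 1), all(qtl$trait <= t))
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps = as.integer(n_snps),
                 family_size = as.integer(family_size),
                 unrelated = unrelated, maf_range = maf_range,
                 traits = traits, lambda = lambda, sigma_g = sigma_g,
                 psi = psi, qtl = qtl, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate genotypes (and pedigree)
#'
#' Founder allele frequencies are drawn per SNP from `maf_range`; founders
#' get Hardy-Weinberg dosages. In family mode each family has its own
#' unrelated sire and dam, and offspring dosages arise by Mendelian
#' sampling of one allele from each parent per SNP.
#'
#' @param cfg a `sim_config`.
#' @return list with `genotypes` (a `genotype_matrix` over the phenotyped
#'   individuals), `pedigree` (data.frame id/sire/dam including founders)
#'   and `maf` (the founder frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- cfg$n_snps; n <- cfg$n_individuals
  maf <- runif(p, cfg$maf_range[1L], cfg$maf_range[2L])
  snp_ids <- sprintf("snp%04d", seq_len(p))
  map <- data.frame(id = snp_ids, chrom = rep(1L, p), pos = seq_len(p) * 1000L,
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  if (cfg$unrelated) {
    dos <- matrix(rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    ids <- sprintf("ind%04d", seq_len(n))
    dimnames(dos) <- list(ids, snp_ids)
    ped <- data.frame(id = ids, sire = "0", dam = "0",
                      stringsAsFactors = FALSE)
    return(list(genotypes = genotype_matrix(dos, map), pedigree = ped,
                maf = maf))
  }
  fam_size <- cfg$family_size
  n_fam <- n %/% fam_size
  transmit <- function(parent_dos, k) {
    # k independent gametes from one parent genotype vector (length p)
    het <- parent_dos == 1L
    base <- matrix(rep(parent_dos / 2, k), k, p, byrow = TRUE)
    if (any(het))
      base[, het] <- matrix(rbinom(k * sum(het), 1L, 0.5), k)
    base
  }
  dos <- matrix(0L, n, p)
  ids <- character(n)
  ped_rows <- vector("list", n_fam)
  row <- 0L
  for (f in seq_len(n_fam)) {
    sire <- rbinom(p, 2L, maf)
    dam <- rbinom(p, 2L, maf)
    kid <- transmit(sire, fam_size) + transmit(dam, fam_size)
    idx <- row + seq_len(fam_size)
    dos[idx, ] <- kid
    ids[idx] <- sprintf("F%03d_O%02d", f, seq_len(fam_size))
    ped_rows[[f]] <- data.frame(
      id = c(sprintf("F%03d_S", f), sprintf("F%03d_D", f), ids[idx]),
      sire = c("0", "0", rep(sprintf("F%03d_S", f), fam_size)),
      dam = c("0", "0", rep(sprintf("F%03d_D", f), fam_size)),
      stringsAsFactors = FALSE)
    row <- row + fam_size
  }
  dimnames(dos) <- list(ids, snp_ids)
  list(genotypes = genotype_matrix(dos, map),
       pedigree = do.call(rbind, ped_rows), maf = maf)
}

#' Simulate phenotypes through the recursive structure
#'
#' Draws polygenic effects with covariance Sigma_g (x) K (via matrix
#' square roots), independent residuals with variances `psi`, adds the QTL
#' direct contributions W s, and propagates everything through the reduced
#' form y = (I - Lambda)^-1 (W s + g + e).
#'
#' @param cfg a `sim_config`.
#' @param g a `genotype_matrix` for the phenotyped individuals.
#' @param K a `kinship_matrix` over the same individuals (NULL for
#'   unrelated, i.e. K = I).
#' @param K_chol optional precomputed lower-triangular factor of K (reuse
#'   across replicates with the same pedigree).
#' @return data.frame of phenotypes with a `truth` attribute recording
#'   lambda, sigma_g, psi, the QTL table and the polygenic values.
#' @export
simulate_phenotypes <- function(cfg, g, K = NULL, K_chol = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(g$dosages)
  t <- length(cfg$traits)
  B <- solve(diag(t) - cfg$lambda)
  # genetic values: Lk Z Lg' has covariance Sigma_g (x) K
  eg <- eigen(cfg$sigma_g, symmetric = TRUE)
  Lg <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), t)
  Zg <- matrix(rnorm(n * t), n, t)
  if (!is.null(K_chol)) {
    gv <- K_chol %*% Zg %*% t(Lg)
  } else if (!is.null(K)) {
    Lk <- t(chol(.sym(unclass(K)) + diag(1e-8, n)))
    gv <- Lk %*% Zg %*% t(Lg)
  } else {
    gv <- Zg %*% t(Lg)
  }
  ev <- matrix(rnorm(n * t), n, t) %*% diag(sqrt(cfg$psi), t)
  qtl_part <- matrix(0, n, t)
  if (!is.null(cfg$qtl) && nrow(cfg$qtl) > 0L) {
    for (r in seq_len(nrow(cfg$qtl)))
      qtl_part[, cfg$qtl$trait[r]] <- qtl_part[, cfg$qtl$trait[r]] +
        g$dosages[, cfg$qtl$snp[r]] * cfg$qtl$effect[r]
  }
  Y <- (qtl_part + gv + ev) %*% t(B)
  colnames(Y) <- cfg$traits
  out <- as.data.frame(Y)
  rownames(out) <- rownames(g$dosages)
  attr(out, "truth") <- list(lambda = cfg$lambda, sigma_g = cfg$sigma_g,
                             psi = cfg$psi, qtl = cfg$qtl,
                             polygenic = gv, seed = cfg$seed)
  out
}

#' Named simulation fixtures
#'
#' Small deterministic datasets with documented ground truth, shared by
#' the test suites and examples:
#' \describe{
#'   \item{null}{no QTL, no structural edges.}
#'   \item{chain}{y1 -> y2 -> y3 (coefficients 2.14, -0.31).}
#'   \item{collider}{y1 -> y2 <- y3, with the trait columns permuted so
#'     that the generative order differs from the column order.}
#'   \item{fully_recursive}{y1 -> y2, y1 -> y3, y2 -> y3 with
#'     coefficients 2.13, -0.17, -0.27.}
#'   \item{paper_like}{the fully recursive structure at n = 1000 with 500
#'     SNPs and 5 QTL of mixed direct/indirect signature, full-sib
#'     families of 10.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @return list with `genotypes`, `phenotypes`, `pedigree`, `K`
#'   (pedigree-based kinship over the phenotyped individuals), `config`
#'   and `truth`.
#' @export
make_fixture <- function(name = c("null", "chain", "collider",
                                  "fully_recursive", "paper_like"),
                         seed = 20181009L) {
  name <- match.arg(name)
  t3 <- c("y1", "y2", "y3")
  lam <- function(l21 = 0, l31 = 0, l32 = 0)
    matrix(c(0, l21, l31, 0, 0, l32, 0, 0, 0), 3L, 3L)
  sg <- 0.43 * (0.5 + 0.5 * diag(3))   # variances 0.43, correlations 0.5
  cfg <- switch(name,
    null = sim_config(600L, 300L, family_size = 6L, traits = t3,
                      lambda = lam(), sigma_g = sg, seed = seed),
    chain = sim_config(600L, 300L, family_size = 6L, traits = t3,
                       lambda = lam(l21 = 2.14, l32 = -0.31),
                       sigma_g = sg, seed = seed),
    # collider y1 -> y2 <- y3: built in the topological order
    # (y1, y3, y2) so lambda is lower-triangular, then the phenotype
    # columns are reported as (y1, y2, y3) to exercise ordering logic
    collider = sim_config(600L, 300L, family_size = 6L,
                          traits = c("y1", "y3", "y2"),
                          lambda = lam(l31 = 1.2, l32 = -0.8),
                          sigma_g = sg, seed = seed),
    fully_recursive = sim_config(600L, 300L, family_size = 6L, traits = t3,
                                 lambda = lam(2.13, -0.17, -0.27),
                                 sigma_g = sg, seed = seed),
    paper_like = sim_config(1000L, 500L, family_size = 10L, traits = t3,
                            lambda = lam(2.13, -0.17, -0.27),
                            sigma_g = sg,
                            qtl = data.frame(
                              snp = c(10L, 110L, 210L, 310L, 310L, 410L),
                              trait = c(1L, 2L, 3L, 1L, 3L, 1L),
                              effect = c(0.45, 0.6, 0.6, 0.5, -0.4, -0.5)),
                            seed = seed)
  )
  sim <- simulate_genotypes(cfg)
  A_full <- nrm_from_pedigree(sim$pedigree)
  K <- kinship_subset(A_full, rownames(sim$genotypes$dosages))
  pheno <- simulate_phenotypes(cfg, sim$genotypes, K)
  truth <- attr(pheno, "truth")
  if (name == "collider") {
    pheno <- pheno[, t3]
    truth$generative_order <- cfg$traits
  }
  list(genotypes = sim$genotypes, phenotypes = pheno,
       pedigree = sim$pedigree, K = K, config = cfg, truth = truth)
}
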