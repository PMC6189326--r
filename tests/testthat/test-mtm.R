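# Multi-trait REML, Gibbs sampling, and the fixed-component SNP scan.

test_that("single-trait REML with K = I partitions the sample variance", {
  set.seed(2)
  n <- 200
  K <- kinship_matrix(diag(n))
  rownames(K) <- colnames(K) <- paste0("s", 1:n)
  ph <- data.frame(y = rnorm(n, sd = 2))
  rownames(ph) <- rownames(K)
  fit <- suppressMessages(fit_mtm_reml(ph, K))
  expect_equal(fit$sigma_g[1, 1] + fit$sigma_e[1, 1], var(ph$y),
               tolerance = 0.05)
  expect_equal(fit$k, 2L)
})

test_that("EM trace is monotone and multi-start REML is deterministic", {
  fx <- fixture("null")
  fit <- cached("mtm_null", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  expect_true(all(diff(fit$trace) > -1e-7 * abs(fit$trace[-1])))

  alt <- suppressMessages(fit_mtm_reml(
    fx$phenotypes, fx$K,
    init = list(sigma_g = diag(2, 3), sigma_e = diag(0.2, 3))))
  expect_lt(abs(alt$logL - fit$logL), 1e-6)
})

test_that("REML recovers a null genetic covariance from unstructured data", {
  # traits simulated with sigma_g = 0: all genetic entries should be small
  cfg <- sim_config(n_individuals = 500L, n_snps = 50L, family_size = 5L,
                    sigma_g = diag(1e-12, 3), psi = c(1, 1, 1), seed = 314L)
  sim <- suppressMessages(simulate_genotypes(cfg))
  A <- suppressMessages(nrm_from_pedigree(sim$pedigree))
  K <- kinship_subset(A, rownames(sim$genotypes$dosages))
  ph <- simulate_phenotypes(cfg, sim$genotypes, K)
  fit <- suppressMessages(fit_mtm_reml(ph, K))
  # sampling sd of a family-design variance component at n=500 is ~0.05
  expect_lt(max(abs(fit$sigma_g)), 0.15)
  expect_equal(fit$sigma_e, unname(cov(as.matrix(ph))), tolerance = 0.15)
})

test_that("information criteria follow the half-negative convention", {
  fake <- list(logL = -100, k = 12, n_records = 100)
  st <- model_fit_stats(fake)
  expect_equal(unname(st["half_neg_aic"]), -112)
  expect_equal(unname(st["half_neg_bic"]), -100 - 6 * log(100))
})

test_that("model comparison requires a shared data fingerprint", {
  fx <- fixture("null")
  fit <- cached("mtm_null", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  tab <- compare_models(list(mtm = fit))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$half_neg_aic, fit$logL - fit$k)

  other <- fit
  other$fingerprint <- "different"
  expect_error(compare_models(list(a = fit, b = other)), "fingerprint")
})

test_that("Gibbs chain bookkeeping, seeding, and posterior recovery behave", {
  fx <- fixture("null")
  K <- precompute_kinship_eigen(fx$K)
  dr <- suppressMessages(fit_mtm_gibbs(fx$phenotypes, K, iterations = 600L,
                                       burn_in = 100L, thin = 5L, seed = 9L))
  expect_equal(dr$n_stored, 100L)
  expect_equal(dim(dr$sigma_g), c(100L, 3L, 3L))

  dr2 <- suppressMessages(fit_mtm_gibbs(fx$phenotypes, K, iterations = 600L,
                                        burn_in = 100L, thin = 5L, seed = 9L))
  expect_identical(dr$sigma_g, dr2$sigma_g)

  expect_error(suppressMessages(fit_mtm_gibbs(fx$phenotypes, K,
                                              priors = list(scale = diag(c(1, -1, 1))))),
               "positive definite")

  # posterior mean of the residual covariance near the reduced-form truth,
  # and Geweke diagnostics inside the convergence band
  # default chain length: mixing between the genetic/residual split is
  # slow, so the diagnostic needs the full default run
  dr3 <- cached("gibbs_null", suppressMessages(
    fit_mtm_gibbs(fx$phenotypes, K, seed = 77L)))
  truth <- fx$truth
  Se_true <- diag(truth$psi)
  pm <- apply(dr3$sigma_e, c(2, 3), mean)
  psd <- apply(dr3$sigma_e, c(2, 3), sd)
  expect_true(all(abs(pm - Se_true) < 4 * psd + 0.05))
  z <- vapply(1:3, function(i) geweke_z(dr3$sigma_e[, i, i]), numeric(1))
  expect_true(all(abs(z) < 3))
})

test_that("the fixed-component scan reduces to OLS when variance is trivial", {
  # t = 1, sigma_g = 0, K = I: estimate equals the least-squares slope
  y <- c(1.1, 1.9, 3.2, 3.8, 5.1)
  w <- c(0, 0, 1, 2, 2)
  K <- kinship_matrix(diag(5)); rownames(K) <- colnames(K) <- paste0("s", 1:5)
  ph <- data.frame(y = y); rownames(ph) <- rownames(K)
  g <- genotype_matrix(matrix(w, 5, 1, dimnames = list(rownames(K), "m1")))
  vc <- list(sigma_g = matrix(1e-12), sigma_e = matrix(1))
  scan <- suppressMessages(mtm_snp_scan(ph, g, K, vc))
  ols <- lm(y ~ w)
  expect_equal(scan$estimate, unname(coef(ols)["w"]), tolerance = 1e-6)

  # zero-variance SNP flagged, not an error
  g0 <- genotype_matrix(matrix(1, 5, 1, dimnames = list(rownames(K), "mono")))
  s0 <- suppressMessages(mtm_snp_scan(ph, g0, K, vc))
  expect_true(is.na(s0$estimate))
})

test_that("scan statistics are scale equivariant", {
  fx <- fixture("null")
  fit <- cached("mtm_null", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  g <- fx$genotypes
  gsub <- genotype_matrix(g$dosages[, 1:20], g$map[1:20, ])
  s1 <- suppressMessages(mtm_snp_scan(fx$phenotypes, gsub, fx$K, fit))
  ph2 <- fx$phenotypes * 2
  fit2 <- list(sigma_g = 4 * fit$sigma_g, sigma_e = 4 * fit$sigma_e)
  s2 <- suppressMessages(mtm_snp_scan(ph2, gsub, fx$K, fit2))
  expect_equal(s2$estimate, 2 * s1$estimate, tolerance = 1e-8)
  expect_equal(s2$se, 2 * s1$se, tolerance = 1e-8)
  expect_equal(s2$t, s1$t, tolerance = 1e-8)
  expect_equal(s2$p, s1$p, tolerance = 1e-8)
})
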