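# SEM fitting, the SNP-effect decomposition, and FDR control.

test_that("the structural fit recovers the generating coefficients with correct signs", {
  fx <- fixture("fully_recursive")
  mtm <- cached("mtm_fr", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  fit <- cached("sem_fr", suppressMessages(
    fit_sem(fx$phenotypes, fx$K, saturated_dag(), mtm = mtm)))
  lam <- fit$edges
  truth <- c("y1 y2" = 2.13, "y1 y3" = -0.17, "y2 y3" = -0.27)
  got <- setNames(lam$lambda, paste(lam$from, lam$to))
  z <- abs(got - truth[names(got)]) / lam$se
  expect_true(all(z < 3))
  expect_gt(got["y1 y2"], 0)
  expect_lt(got["y1 y3"], 0)
  expect_lt(got["y2 y3"], 0)
  expect_equal(fit$k, 3 + 6 + 3)
})

test_that("a saturated SEM and the MTM reach the same restricted likelihood", {
  fx <- fixture("fully_recursive")
  mtm <- cached("mtm_fr", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  fit <- cached("sem_fr", suppressMessages(
    fit_sem(fx$phenotypes, fx$K, saturated_dag(), mtm = mtm)))
  expect_lt(abs(fit$logL - mtm$logL), 1e-4)
  tab <- compare_models(list(mtm = mtm, sem = fit))
  # equal logL but different parameter counts can flip the AIC ordering
  expect_equal(tab$k, c(12, 12))
})

test_that("with an empty DAG and diagonal components the likelihood factorizes", {
  set.seed(21)
  n <- 300
  K <- kinship_matrix(diag(n))
  rownames(K) <- colnames(K) <- paste0("s", 1:n)
  fam <- rep(1:(n / 5), each = 5)
  # give K family structure so the variance split is identifiable
  Kb <- kinship_matrix(0.5 * outer(fam, fam, "==") + 0.5 * diag(n))
  rownames(Kb) <- colnames(Kb) <- rownames(K)
  ph <- as.data.frame(matrix(rnorm(n * 3), n, 3))
  colnames(ph) <- c("y1", "y2", "y3")
  rownames(ph) <- rownames(K)
  fit <- suppressMessages(fit_sem(ph, Kb, empty_dag(),
                                  genetic_covariance = "diagonal"))
  expect_equal(nrow(fit$edges), 0L)
  single <- vapply(1:3, function(j) {
    suppressMessages(fit_mtm_reml(ph[, j, drop = FALSE], Kb))$logL
  }, numeric(1))
  expect_lt(abs(fit$logL - sum(single)), 0.02)

  expect_error(suppressMessages(
    fit_sem(ph, Kb, empty_dag(), residual_covariance = "unstructured")),
    "identifiable")
})

test_that("path enumeration lists exactly the recursive-model paths", {
  Lam <- matrix(0, 3, 3, dimnames = list(paste0("y", 1:3), paste0("y", 1:3)))
  Lam[2, 1] <- 2.13; Lam[3, 1] <- -0.17; Lam[3, 2] <- -0.27
  d <- c(1, 1, 1)
  p3 <- enumerate_indirect_paths(NULL, Lam, d, 3)
  expect_setequal(p3$path, c("y1->y2->y3", "y2->y3", "y1->y3"))
  expect_equal(sum(p3$contribution),
               -0.27 * 2.13 * 1 - 0.27 * 1 - 0.17 * 1, tolerance = 1e-12)

  expect_equal(nrow(enumerate_indirect_paths(NULL, matrix(0, 3, 3), d, 2)), 0L)

  chainL <- matrix(0, 3, 3); chainL[2, 1] <- 2.13; chainL[3, 2] <- -0.27
  pc <- enumerate_indirect_paths(NULL, chainL, c(1, 0, 0), 3)
  expect_equal(pc$path, "y1->y2->y3")
  expect_equal(pc$contribution, -0.27 * 2.13, tolerance = 1e-12)
})

test_that("the reduced form is the oracle for the path-sum decomposition", {
  Lam <- matrix(0, 3, 3)
  Lam[2, 1] <- 2; Lam[3, 1] <- -0.2; Lam[3, 2] <- -0.3
  expect_equal(total_effect_reduced_form(Lam, c(1, 0.5, 0.1)),
               c(1, 2.5, -0.85), tolerance = 1e-12)
  expect_equal(total_effect_reduced_form(matrix(0, 2, 2), c(3, -1)),
               c(3, -1))

  set.seed(33)
  for (i in 1:100) {
    t <- sample(3:6, 1)
    L <- random_dag_lambda(t)
    d <- rnorm(t)
    dec <- decompose_snp_effect(NULL, L, d)
    tot <- dec$table$estimate[dec$table$effect_type == "total"]
    expect_lt(max(abs(tot - total_effect_reduced_form(L, d))), 1e-12)
    ind <- dec$table$estimate[dec$table$effect_type == "indirect"]
    expect_lt(max(abs(tot - d - ind)), 1e-12)
  }
})

test_that("delta-method errors collapse correctly when the structure is empty", {
  d <- c(0.4, -0.2, 0.1); se <- c(0.1, 0.2, 0.15)
  dec <- decompose_snp_effect(NULL, matrix(0, 3, 3), d, se)
  tab <- dec$table
  expect_equal(tab$estimate[tab$effect_type == "indirect"], rep(0, 3))
  expect_equal(tab$estimate[tab$effect_type == "total"], d)
  expect_equal(tab$se[tab$effect_type == "total"], se)
})

test_that("indirect effects can flip the sign of the total", {
  Lam <- matrix(0, 2, 2); Lam[2, 1] <- -3
  d <- c(1, 0.5)           # direct on y2 positive...
  dec <- decompose_snp_effect(NULL, Lam, d)
  tot2 <- dec$table$estimate[dec$table$effect_type == "total"][2]
  expect_lt(tot2, 0)       # ...but the mediated path drives the total negative
})

test_that("scan direct effects are null for traits the QTL does not touch", {
  fx <- fixture("chain")
  mtm <- cached("mtm_chain", suppressMessages(fit_mtm_reml(fx$phenotypes, fx$K)))
  fit <- cached("sem_chain", suppressMessages(
    fit_sem(fx$phenotypes, fx$K, chain_dag(), mtm = mtm)))
  scan <- cached("scan_chain", suppressMessages(
    sem_snp_scan(fx$phenotypes, fx$genotypes, fx$K, fit)))
  # no QTL in the chain fixture: every trait equation should be calibrated
  for (tr in c("y1", "y2", "y3")) {
    rate <- mean(abs(scan$t[scan$trait == tr]) > 1.96)
    expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  }
})

test_that("with a diagonal fit the SEM scan equals independent single-trait scans", {
  fx <- fixture("null")
  g <- fx$genotypes
  gsub <- genotype_matrix(g$dosages[, 1:30], g$map[1:30, ])
  fit <- list(lambda = matrix(0, 3, 3,
                              dimnames = list(colnames(fx$phenotypes),
                                              colnames(fx$phenotypes))),
              sigma_g = diag(c(0.4, 0.5, 0.6)), psi = c(1, 1.1, 0.9),
              traits = colnames(fx$phenotypes), dag = empty_dag(),
              edges = data.frame(from = character(0), to = character(0)),
              lambda_cov = NULL)
  class(fit) <- c("sem_fit", "mixed_model_fit")
  scan <- suppressMessages(sem_snp_scan(fx$phenotypes, gsub, fx$K, fit))
  for (j in 1:3) {
    vc1 <- list(sigma_g = fit$sigma_g[j, j, drop = FALSE],
                sigma_e = matrix(fit$psi[j]))
    s1 <- suppressMessages(mtm_snp_scan(fx$phenotypes[, j, drop = FALSE],
                                        gsub, fx$K, vc1))
    expect_equal(scan$estimate[scan$trait == fit$traits[j]], s1$estimate,
                 tolerance = 1e-8)
    expect_equal(scan$se[scan$trait == fit$traits[j]], s1$se,
                 tolerance = 1e-8)
  }
})

test_that("Benjamini-Hochberg matches the hand-run step-up procedure", {
  res <- bh_fdr(c(0.001, 0.02, 0.03, 0.5))
  expect_equal(res$n_rejected, 3L)
  expect_equal(res$threshold_neglog10p, -log10(0.03))
  expect_equal(res$q, p.adjust(c(0.001, 0.02, 0.03, 0.5), "BH"))

  none <- bh_fdr(rep(1, 10))
  expect_equal(none$n_rejected, 0L)
  expect_true(is.na(none$threshold_neglog10p))

  # independent step-up oracle on random p-values
  set.seed(12)
  p <- runif(200)^2
  m <- length(p)
  ord <- order(p)
  thresh <- max(c(0, which(p[ord] <= seq_len(m) * 0.05 / m)))
  expect_equal(bh_fdr(p)$n_rejected, thresh)
})

test_that("decompose_scan writes per-type q-values and path strings", {
  fx <- fixture("chain")
  fit <- cached("sem_chain", suppressMessages(
    fit_sem(fx$phenotypes, fx$K, chain_dag(),
            mtm = cached("mtm_chain", suppressMessages(
              fit_mtm_reml(fx$phenotypes, fx$K))))))
  scan <- cached("scan_chain", suppressMessages(
    sem_snp_scan(fx$phenotypes, fx$genotypes, fx$K, fit)))
  dec <- decompose_scan(fit, scan)
  expect_setequal(unique(dec$effect_type), c("direct", "indirect", "total"))
  expect_equal(nrow(dec), 3 * 3 * ncol(fx$genotypes$dosages))
  ind3 <- dec[dec$effect_type == "indirect" & dec$trait == "y3", ]
  # both chain routes into y3 appear: the two-step path and the y2 leg
  expect_true(all(ind3$paths == "y1->y2->y3;y2->y3"))
  # totals equal direct + indirect row-wise
  wide <- split(dec, dec$effect_type)
  expect_equal(wide$total$estimate,
               wide$direct$estimate + wide$indirect$estimate,
               tolerance = 1e-10)
  expect_true(all(dec$q >= dec$p - 1e-12, na.rm = TRUE))
})
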