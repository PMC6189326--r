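# Partial correlations, HPD intervals, and the IC structure search.

test_that("partial correlations match the recursion formula and edge cases", {
  S <- matrix(0.5, 3, 3); diag(S) <- 1
  expect_equal(residual_partial_correlation(S, c(1, 2), 3), 1 / 3,
               tolerance = 1e-12)
  expect_equal(residual_partial_correlation(S, c(1, 2)), 0.5)

  D <- diag(c(1, 2, 3))
  for (h in list(integer(0), 3L))
    expect_equal(residual_partial_correlation(D, c(1, 2), h), 0)

  expect_error(residual_partial_correlation(S, c(1, 2), c(2)), "exclude")
  sing <- matrix(1, 3, 3)
  expect_error(residual_partial_correlation(sing, c(1, 2), 3), "singular")
})

test_that("HPD intervals agree exactly with brute-force window search", {
  h <- hpd_interval(1:100, 0.95)
  expect_equal(c(h$lower, h$upper), c(1, 95))
  expect_equal(hpd_interval(rep(3.3, 20), 0.9)$lower, 3.3)
  expect_equal(hpd_interval(rep(3.3, 20), 0.9)$upper, 3.3)

  set.seed(4)
  for (i in 1:25) {
    x <- switch(1 + i %% 3,
                rnorm(sample(10:500, 1)),
                rexp(sample(10:500, 1)),
                c(rnorm(100), rnorm(50, 6)))
    cv <- runif(1, 0.5, 0.99)
    got <- hpd_interval(x, cv)
    expect_equal(c(got$lower, got$upper), hpd_brute(x, cv))
  }
})

test_that("dependence decisions follow the zero-in-interval rule", {
  set.seed(8)
  expect_equal(dependence_decision(rnorm(500, 0.5, 0.1), 0.95), "dependent")
  expect_equal(dependence_decision(rnorm(500, 0, 0.1), 0.95), "independent")
  expect_equal(dependence_decision(seq(0.01, 1, length.out = 100), 0.5),
               "dependent")
})

test_that("IC with a d-separation oracle handles chain, collider and complete graphs", {
  traits <- c("y1", "y2", "y3")
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  s <- ic_algorithm(traits, dsep_oracle(chain))
  expect_equal(skeleton_of(s), skeleton_of(chain))
  expect_length(found_vstructures(s), 0)
  expect_true(all(s$amat[s$amat != 0] == 1L))  # both edges undirected

  collider <- matrix(0, 3, 3); collider[1, 2] <- collider[3, 2] <- 1
  s2 <- ic_algorithm(traits, dsep_oracle(collider))
  expect_equal(s2$amat[1, 2], 2L)
  expect_equal(s2$amat[3, 2], 2L)
  expect_equal(s2$amat[1, 3] + s2$amat[3, 1], 0L)

  s3 <- ic_algorithm(traits, function(i, j, h) TRUE)
  expect_true(all(skeleton_of(s3)[upper.tri(diag(3))]))
  expect_true(all(s3$amat[s3$amat != 0] == 1L))
})

test_that("IC recovers skeleton and v-structures for every DAG on 3 nodes", {
  dags <- all_dags(3)
  expect_length(dags, 25)   # the number of labeled DAGs on 3 nodes
  for (adj in dags) {
    s <- ic_algorithm(c("y1", "y2", "y3"), dsep_oracle(adj))
    expect_equal(skeleton_of(s), skeleton_of(adj))
    expect_equal(found_vstructures(s), true_vstructures(adj))
  }
})

test_that("order completion yields the expected recursive DAGs", {
  comp <- ic_algorithm(c("BM", "BW", "HHP"), function(i, j, h) TRUE)
  dag <- orient_with_order(comp, c("BM", "BW", "HHP"))
  expect_equal(dag$status, "dag")
  e <- structure_edges(dag)
  expect_setequal(paste(e$from, e$to), c("BM BW", "BM HHP", "BW HHP"))
  expect_true(all(e$status == "directed"))

  # chain skeleton oriented along the order
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  pd <- ic_algorithm(c("y1", "y2", "y3"), dsep_oracle(chain))
  cd <- orient_with_order(pd, c("y1", "y2", "y3"))
  expect_equal(cd$amat[1, 2], 2L)
  expect_equal(cd$amat[2, 3], 2L)

  # a directed edge fighting the order is refused
  collider <- matrix(0, 3, 3); collider[1, 2] <- collider[3, 2] <- 1
  pc <- ic_algorithm(c("y1", "y2", "y3"), dsep_oracle(collider))
  expect_error(orient_with_order(pc, c("y2", "y1", "y3")), "contradicts")
  # a consistent order passes through unchanged
  same <- orient_with_order(pc, c("y1", "y3", "y2"))
  expect_equal(same$amat, pc$amat)
})

test_that("edge sets shrink monotonically as HPD coverage grows", {
  fx <- fixture("chain")
  K <- precompute_kinship_eigen(fx$K)
  dr <- cached("gibbs_chain", suppressMessages(
    fit_mtm_gibbs(fx$phenotypes, K, iterations = 3000L, burn_in = 1000L,
                  thin = 5L, seed = 123L)))
  edges_at <- function(hpd) {
    s <- infer_structure(dr, hpd = hpd)
    e <- structure_edges(s)
    paste(pmin(e$from, e$to), pmax(e$from, e$to))
  }
  e75 <- edges_at(0.75); e85 <- edges_at(0.85); e95 <- edges_at(0.95)
  expect_true(all(e95 %in% e85))
  expect_true(all(e85 %in% e75))
})

test_that("d-separation answers standard textbook queries", {
  # chain: 1 ind 3 given 2, dependent marginally
  chain <- matrix(0, 3, 3); chain[1, 2] <- chain[2, 3] <- 1
  expect_false(dsep(chain, 1, 3))
  expect_true(dsep(chain, 1, 3, 2))
  # collider: 1 ind 3 marginally, dependent given the collider
  col <- matrix(0, 3, 3); col[1, 2] <- col[3, 2] <- 1
  expect_true(dsep(col, 1, 3))
  expect_false(dsep(col, 1, 3, 2))
})
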