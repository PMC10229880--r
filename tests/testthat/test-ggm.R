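test_that("sample_correlation validates, names methods, and repairs non-PD input", {
  sc <- indep_scores(400, p = 4, seed = 2)
  S <- sample_correlation(sc)
  expect_s3_class(S, "correlation_matrix")
  expect_equal(diag(S$values), rep(1, 4), ignore_attr = TRUE)
  expect_equal(S$values, t(S$values))
  expect_equal(S$method, "pearson")

  # independence: small off-diagonals at large n
  big <- indep_scores(10000, p = 4, seed = 3)
  Sb <- sample_correlation(big)$values
  expect_lt(max(abs(Sb[upper.tri(Sb)])), 0.05)

  # constant column rejected by name
  bad <- sc
  bad$v2 <- 1
  expect_error(sample_correlation(bad), "v2")

  # duplicated column -> singular matrix -> PD repair with warning
  dup <- sc
  dup$v4 <- dup$v3
  expect_warning(Sd <- sample_correlation(dup), "positive definite")
  expect_true(Sd$repaired)
  expect_gt(Sd$values["v3", "v4"], 0.999)
  ev <- eigen(Sd$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("sample correlations recover a planted covariance", {
  spec <- make_true_network()
  sc <- simulate_cohort(make_true_network(targets = NULL), n = 5000, seed = 4)
  S <- sample_correlation(sc)$values
  expect_lt(max(abs(S - spec$sigma)), 0.05)
})

test_that("lambda_path_grid spans max|off-diagonal| down to min_ratio of it", {
  S <- rand_cor(5, seed = 10)
  lmax <- max(abs(S[upper.tri(S)]))
  grid <- lambda_path_grid(S, n_lambda = 100, min_ratio = 0.01)
  expect_length(grid, 100)
  expect_equal(grid[1], lmax)
  expect_equal(grid[100], lmax / 100)
  expect_true(all(diff(grid) < 0))
  expect_warning(g0 <- lambda_path_grid(diag(3)), "zero")
  expect_equal(g0, 0)
})

test_that("glasso_fit matches the direct-inversion oracle at lambda = 0", {
  S <- rand_cor(3, seed = 21)
  K <- glasso_fit(S, 0)
  expect_lt(max(abs(K$values - solve(S))), 1e-6)
  # identity input is a fixed point for any penalty
  for (lam in c(0, 0.1, 1)) {
    expect_equal(glasso_fit(diag(4), lam)$values, diag(4), ignore_attr = TRUE)
  }
})

test_that("penalties at or above max|off-diagonal| give the empty graph", {
  S <- rand_cor(6, seed = 22)
  lmax <- max(abs(S[upper.tri(S)]))
  for (lam in c(lmax, lmax * 1.5)) {
    K <- glasso_fit(S, lam)$values
    expect_true(all(K[upper.tri(K)] == 0))
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("gaussian_loglik has its closed form, maximum, and n-scaling", {
  expect_equal(gaussian_loglik(diag(2), diag(2), 10), -10)
  S <- rand_cor(3, seed = 30)
  at_opt <- gaussian_loglik(solve(S), S, 50)
  for (s in 1:5) {
    pert <- solve(S) + rand_cor(3, seed = 100 + s) * 0.1
    expect_lt(gaussian_loglik(pert, S, 50), at_opt)
  }
  expect_equal(gaussian_loglik(solve(S), S, 100), 2 * at_opt)
  expect_error(gaussian_loglik(diag(c(1, -1)), diag(2), 10), "positive definite")
})

test_that("ebic_score reduces to BIC at gamma 0 and penalizes by edge count", {
  S <- rand_cor(3, seed = 31)
  K <- glasso_fit(S, 0.05)
  n <- 200
  E <- sum(K$values[upper.tri(K$values)] != 0)
  L <- gaussian_loglik(K, S, n)
  expect_equal(ebic_score(K, S, n, gamma = 0), -2 * L + E * log(n))

  # empty graph: EBIC = -2L for every gamma
  lmax <- max(abs(S[upper.tri(S)]))
  K0 <- glasso_fit(S, lmax * 1.1)
  L0 <- gaussian_loglik(K0, S, n)
  expect_equal(ebic_score(K0, S, n, gamma = 0.5), -2 * L0)
  expect_equal(ebic_score(K0, S, n, gamma = 2), -2 * L0)

  # hand arithmetic: 3 nodes, E = 2, n = 100, gamma = 0.5
  Kh <- matrix(c(1, 0.2, 0.1, 0.2, 1, 0, 0.1, 0, 1), 3, 3)
  penalty <- ebic_score(Kh, diag(3), 100, gamma = 0.5) +
    2 * gaussian_loglik(Kh, diag(3), 100)
  expect_equal(penalty, 2 * log(100) + 4 * 0.5 * 2 * log(3))
})

test_that("precision_to_pcor matches the Schur-complement oracle", {
  expect_equal(precision_to_pcor(diag(c(1, 2, 3))), matrix(0, 3, 3))
  K2 <- matrix(c(1, -0.3, -0.3, 1), 2, 2)
  expect_equal(precision_to_pcor(K2)[1, 2], 0.3)
  for (s in 1:5) {
    Sig <- rand_cor(4, seed = 200 + s)
    K <- solve(Sig)
    P <- precision_to_pcor(K)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        expect_lt(abs(P[i, j] - pcor_oracle(Sig, i, j)), 1e-8)
      }
    }
  }
})

test_that("estimate_network selects the empty model on independent data", {
  # EBIC with gamma = 0.5 is conservative: across seeds the selected model is
  # empty nearly always, and any surviving spurious edge is tiny
  empties <- 0
  for (s in 40:44) {
    net <- estimate_network(indep_scores(5000, p = 6, seed = s))
    expect_s3_class(net, "pcor_network")
    expect_lt(max(abs(net$weights)), 0.06)
    if (all(net$weights == 0)) empties <- empties + 1
  }
  expect_gte(empties, 4)
})

test_that("network weights are a symmetric zero-diagonal matrix in (-1, 1)", {
  spec <- make_true_network()
  sc <- simulate_cohort(spec, n = 600, seed = 41)
  net <- estimate_network(sc)
  W <- net$weights
  expect_equal(W, t(W))
  expect_equal(diag(W), rep(0, 14), ignore_attr = TRUE)
  expect_true(all(abs(W) < 1))
  expect_lte(glance(net)$n_edges, 14 * 13 / 2)
  # edge count along the stored path is non-increasing in lambda
  path <- net$path # ordered by decreasing lambda
  expect_true(all(diff(path$n_edges) >= 0))
  expect_true(all(diff(path$lambda) < 0))
})

test_that("the selected sparsity pattern is equivariant to node reordering", {
  spec <- make_true_network()
  sc6 <- simulate_cohort(spec, n = 800, seed = 42)
  keep <- c("A1", "A2", "A3", "IGD3", "IGD5", "IGD6")
  sub <- bridgenet:::new_node_scores(
    sc6[c("respondent_id", keep)], node_communities(sc6)[keep]
  )
  perm <- rev(keep)
  sub_perm <- bridgenet:::new_node_scores(
    sc6[c("respondent_id", perm)], node_communities(sc6)[perm]
  )
  net_a <- estimate_network(sub)
  net_b <- estimate_network(sub_perm)
  expect_equal(net_a$weights[keep, keep] != 0, net_b$weights[keep, keep] != 0)
  # weights agree up to the coordinate-descent convergence tolerance
  expect_equal(net_a$weights[keep, keep], net_b$weights[keep, keep],
               tolerance = 1e-3)
})

test_that("a lambda = 0 refit equals unregularized partial correlations", {
  sc <- indep_scores(300, p = 5, seed = 43)
  S <- sample_correlation(sc)
  P_glasso <- precision_to_pcor(glasso_fit(S, 0))
  P_direct <- precision_to_pcor(solve(S$values))
  expect_lt(max(abs(P_glasso - P_direct)), 1e-6)
})

test_that("as_pcor_network enforces the container invariants", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  comm <- c(a = "g1", b = "g2")
  expect_s3_class(as_pcor_network(W, comm), "pcor_network")
  Wbad <- W; Wbad[1, 2] <- 0.4
  expect_error(as_pcor_network(Wbad, comm), "symmetric")
  Wdiag <- W; diag(Wdiag) <- 1
  expect_error(as_pcor_network(Wdiag, comm), "diagonal")
  Wbig <- W; Wbig[1, 2] <- Wbig[2, 1] <- 1
  expect_error(as_pcor_network(Wbig, comm), "strictly")
  expect_error(as_pcor_network(W, c(a = "g1")), "communities")
})
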