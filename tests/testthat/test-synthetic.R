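test_that("an empty planted structure gives an identity model", {
  labels <- c("a", "b", "c")
  P <- matrix(0, 3, 3, dimnames = list(labels, labels))
  spec <- make_true_network(
    pcor = P, communities = setNames(c("g1", "g1", "g2"), labels),
    targets = NULL
  )
  expect_equal(spec$precision, diag(3), ignore_attr = TRUE)
  expect_equal(spec$sigma, diag(3), ignore_attr = TRUE)
  expect_equal(spec$shrink_factor, 1)
})

test_that("the default preset mirrors the published structure", {
  spec <- make_true_network()
  expect_setequal(spec$bridge_nodes, c("A2", "A3", "IGD5"))
  P <- spec$pcor
  comm <- spec$communities
  cross <- outer(comm, comm, `!=`)
  # largest cross-community weight is 0.12 at the panic-disorder/escape pair
  expect_equal(max(P[cross]), 0.12)
  expect_equal(P["A3", "IGD5"], 0.12)
  # 23 planted cross edges, 20 positive
  ut_cross <- cross & upper.tri(P)
  expect_equal(sum(P[ut_cross] != 0), 23)
  expect_equal(sum(P[ut_cross] > 0), 20)
  # implied partial correlations are self-consistent with the precision matrix
  expect_lt(max(abs(precision_to_pcor(spec$precision) - P)), 1e-10)
  # calibrated thresholds are strictly increasing for every node
  for (th in spec$thresholds) {
    expect_true(all(diff(th$thresholds) > 0))
  }
})

test_that("simulated cohorts are reproducible and leave the RNG alone", {
  spec <- make_true_network()
  set.seed(777)
  before <- .Random.seed
  a <- simulate_cohort(spec, n = 50, seed = 5)
  expect_identical(before, .Random.seed)
  b <- simulate_cohort(spec, n = 50, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(simulate_cohort(spec, n = 50), "seed")
})

test_that("independent latents produce uncorrelated Likert scores", {
  labels <- paste0("v", 1:4)
  P <- matrix(0, 4, 4, dimnames = list(labels, labels))
  spec <- make_true_network(
    pcor = P,
    communities = setNames(rep(c("g1", "g2"), 2), labels),
    targets = tibble::tibble(node = labels, mean = 2.5, sd = 1)
  )
  sc <- simulate_cohort(spec, n = 10000, seed = 6)
  S <- cor(score_matrix(sc))
  expect_lt(max(abs(S[upper.tri(S)])), 0.05)
})

test_that("discretization matches the published node means and SDs", {
  spec <- make_true_network()
  sc <- simulate_cohort(spec, n = 5000, seed = 7)
  d <- descriptive_stats(sc)
  ref <- published_descriptives()
  ord <- match(ref$node, d$node)
  expect_lt(max(abs(d$mean[ord] - ref$mean)), 0.15)
  expect_lt(max(abs(d$sd[ord] - ref$sd)), 0.2)
})

test_that("item-level simulation feeds the scoring pipeline", {
  spec <- make_true_network()
  items <- simulate_cohort(spec, n = 300, seed = 8, level = "item")
  expect_named(items, c("respondent_id", paste0("s", 1:19), paste0("igd", 1:9)))
  resp <- load_item_responses(items)
  expect_equal(resp$retention, 100)
  sc <- score_scales(resp)
  expect_equal(setdiff(names(sc), "respondent_id"),
               c(paste0("A", 1:5), paste0("IGD", 1:9)))
  # IGD singleton scoring at item level equals node-level discretization
  direct <- simulate_cohort(spec, n = 300, seed = 8)
  expect_equal(sc$IGD3, direct$IGD3)
})

test_that("discretization attenuates correlations on average", {
  spec <- make_true_network()
  latent <- simulate_cohort(make_true_network(targets = NULL), n = 10000, seed = 9)
  likert <- simulate_cohort(spec, n = 10000, seed = 9)
  r_latent <- cor(score_matrix(latent))
  r_likert <- cor(score_matrix(likert))
  ut <- upper.tri(r_latent)
  expect_lt(mean(abs(r_likert[ut])), mean(abs(r_latent[ut])))
})

test_that("recovery metrics score perfect, empty, and estimated networks", {
  spec <- strong_spec()
  perfect <- recovery_metrics(spec, true_pcor_network(spec))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$mae_nonzero, 0)
  expect_equal(perfect$bei_rank_cor, 1)

  W0 <- spec$pcor * 0
  empty <- recovery_metrics(spec, as_pcor_network(W0, spec$communities))
  expect_equal(empty$sensitivity, 0)
  expect_equal(empty$specificity, 1)

  est <- estimate_network(simulate_cohort(spec, n = 2000, seed = 10))
  m <- recovery_metrics(spec, est)
  expect_gte(m$sensitivity, 0.8)
  expect_gte(m$bei_rank_cor, 0.8)

  bad <- as_pcor_network(
    matrix(0, 2, 2, dimnames = list(c("x", "y"), c("x", "y"))),
    c(x = "g1", y = "g2")
  )
  expect_error(recovery_metrics(spec, bad), "labels")
})

test_that("estimation error on planted edges shrinks with sample size", {
  spec <- strong_spec()
  mae_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      est <- estimate_network(simulate_cohort(spec, n = n, seed = s))
      recovery_metrics(spec, est)$mae_nonzero
    }, numeric(1))
  }
  seeds <- 101:105
  expect_lt(median(mae_at(4000, seeds)), median(mae_at(250, seeds)))
})

test_that("a structure that cannot be made positive definite is rejected", {
  labels <- letters[1:4]
  P <- matrix(0.95, 4, 4, dimnames = list(labels, labels))
  diag(P) <- 0
  expect_error(
    make_true_network(pcor = P,
                      communities = setNames(rep("g1", 4), labels),
                      targets = NULL),
    "positive definite"
  )
})
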