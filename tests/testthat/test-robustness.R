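test_that("edge bootstrap is reproducible and respects CI ordering", {
  spec <- strong_spec()
  sc <- simulate_cohort(spec, n = 300, seed = 31)
  b1 <- bootstrap_edge_ci(sc, B = 20, seed = 32)
  b2 <- bootstrap_edge_ci(sc, B = 20, seed = 32)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(tidy(b1), tidy(b2))
  expect_true(all(b1$lower <= b1$upper))
  expect_equal(dim(b1$replicates), c(20, 15))
  expect_error(bootstrap_edge_ci(sc, B = 20), "seed")
})

test_that("edges with constant replicates get zero-width intervals", {
  sc <- indep_scores(800, p = 5, seed = 50)
  b <- bootstrap_edge_ci(sc, B = 30, seed = 8)
  widths <- b$upper - b$lower
  constant <- apply(b$replicates, 2, function(col) length(unique(col)) == 1)
  expect_true(all(widths[constant] == 0))
  # independent data: the overwhelming majority of edges never enter any
  # replicate's model
  expect_gte(sum(constant), 5)
})

test_that("CI width shrinks with sample size on planted data", {
  spec <- strong_spec()
  s_small <- simulate_cohort(spec, n = 250, seed = 34)
  s_big <- simulate_cohort(spec, n = 2000, seed = 34)
  b_small <- bootstrap_edge_ci(s_small, B = 40, seed = 35)
  b_big <- bootstrap_edge_ci(s_big, B = 40, seed = 35)
  expect_lt(median(b_big$upper - b_big$lower),
            median(b_small$upper - b_small$lower))
})

test_that("case-dropping bootstrap tracks BEI stability", {
  spec <- strong_spec()
  sc <- simulate_cohort(spec, n = 500, seed = 31)
  cd <- case_drop_bootstrap(sc, grid = seq(0.1, 0.7, 0.2), B = 30, seed = 33)
  expect_s3_class(cd, "case_drop")
  expect_true(all(cd$replicates$correlation >= -1 &
                    cd$replicates$correlation <= 1, na.rm = TRUE))
  smry <- tidy(cd)
  # strong planted structure: high correlations throughout, declining with q
  expect_gt(min(smry$median_cor), 0.8)
  expect_gte(smry$median_cor[1], smry$median_cor[nrow(smry)])
  # reproducibility
  cd2 <- case_drop_bootstrap(sc, grid = seq(0.1, 0.7, 0.2), B = 30, seed = 33)
  expect_identical(cd$replicates, cd2$replicates)
})

test_that("subsamples smaller than p + 1 are skipped with a warning", {
  spec <- strong_spec()
  sc <- simulate_cohort(spec, n = 30, seed = 36)
  w <- capture_warnings(
    cd <- case_drop_bootstrap(sc, grid = c(0.2, 0.8), B = 5, seed = 37)
  )
  expect_match(w, "skipped", all = FALSE)
  expect_setequal(unique(cd$replicates$proportion), 0.2)
})

test_that("a constant BEI vector yields missing correlations and a warning", {
  # independent Likert-free noise: the selected network is (nearly) always
  # empty, so every replicate BEI vector is constant zero
  sc <- indep_scores(800, p = 5, seed = 50)
  expect_warning(
    cd <- case_drop_bootstrap(sc, grid = c(0.2, 0.4), B = 10, seed = 51),
    "constant BEI"
  )
  expect_true(anyNA(cd$replicates$correlation))
  expect_equal(cs_coefficient(cd)$value, 0)
})

test_that("cs_coefficient finds the break point and is monotone in its threshold", {
  fake <- function(cors_by_q) {
    reps <- dplyr::bind_rows(lapply(names(cors_by_q), function(q) {
      tibble::tibble(proportion = as.numeric(q),
                     replicate = seq_along(cors_by_q[[q]]),
                     correlation = cors_by_q[[q]])
    }))
    structure(
      list(replicates = reps, full_bei = NULL,
           grid = as.numeric(names(cors_by_q)), B = 20, seed = 1,
           cor_method = "pearson", n = 100),
      class = "case_drop"
    )
  }
  # all correlations 1 -> CS is the grid maximum
  all_one <- fake(setNames(
    rep(list(rep(1, 20)), 5), c("0.1", "0.2", "0.3", "0.4", "0.5")
  ))
  expect_equal(cs_coefficient(all_one)$value, 0.5)

  # condition holds up to 0.4, fails at 0.45 -> CS = 0.4
  broken <- fake(list(
    "0.1" = rep(0.9, 20), "0.2" = rep(0.9, 20), "0.3" = rep(0.9, 20),
    "0.4" = c(rep(0.9, 19), 0.75),
    "0.45" = c(rep(0.9, 15), rep(0.5, 5)),
    "0.5" = rep(0.9, 20)
  ))
  expect_equal(cs_coefficient(broken)$value, 0.4)
  # the later recovery at 0.5 must not produce a non-monotone maximum
  expect_lt(cs_coefficient(broken)$value, 0.5)

  # raising the correlation threshold can only lower the CS
  mid <- fake(list(
    "0.1" = rep(0.9, 20), "0.2" = rep(0.6, 20), "0.3" = rep(0.6, 20)
  ))
  expect_lte(cs_coefficient(mid, cor_threshold = 0.7)$value,
             cs_coefficient(mid, cor_threshold = 0.5)$value)
  expect_equal(cs_coefficient(mid, cor_threshold = 0.5)$value, 0.3)
  expect_equal(cs_coefficient(mid, cor_threshold = 0.7)$value, 0.1)
})

test_that("difference tests flag separated edges and stay symmetric", {
  spec <- strong_spec()
  sc <- simulate_cohort(spec, n = 500, seed = 31)
  b <- bootstrap_edge_ci(sc, B = 40, seed = 32)
  dt <- difference_tests(b, "edge")
  expect_equal(dt$flags, t(dt$flags))
  # planted 0.35 edge vs planted zero edge: clearly different
  prs <- tidy(dt)
  row <- dplyr::filter(prs, .data$a == "L1--L2", .data$b == "L1--R3")
  expect_true(row$different)

  # identical replicate series are never "different"
  sc0 <- indep_scores(800, p = 5, seed = 50)
  b0 <- bootstrap_edge_ci(sc0, B = 20, seed = 8)
  dt_bei <- difference_tests(b0, "bei")
  expect_false(any(tidy(dt_bei)$different))
  expect_equal(nrow(tidy(dt_bei)), choose(5, 2))
})
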