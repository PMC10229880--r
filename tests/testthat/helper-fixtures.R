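# Small fixtures shared across test files. Everything is built in code.

# two toy scales: X with 2 two-item dimensions (codes 0-3), Y with 2 singleton
# items (codes 1-5) -> 4 nodes X1, X2, Y1, Y2 in two communities
toy_defs <- function() {
  list(
    x = scale_definition(
      "X", items = c("x1", "x2", "x3", "x4"), level_codes = 0:3,
      dimensions = list(d1 = c("x1", "x2"), d2 = c("x3", "x4")),
      community = "left", node_prefix = "X"
    ),
    y = scale_definition(
      "Y", items = c("y1", "y2"), level_codes = 1:5,
      dimensions = list(e1 = "y1", e2 = "y2"),
      community = "right", node_prefix = "Y"
    )
  )
}

toy_items <- function(n = 20, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    x1 = sample(0:3, n, TRUE), x2 = sample(0:3, n, TRUE),
    x3 = sample(0:3, n, TRUE), x4 = sample(0:3, n, TRUE),
    y1 = sample(1:5, n, TRUE), y2 = sample(1:5, n, TRUE)
  ))
}

# hand-built 4-node network, two communities of 2; node a has cross edges
# 0.3 (a-c) and -0.1 (a-d); one within edge b-a 0.2
toy_network <- function() {
  labels <- c("a", "b", "c", "d")
  W <- matrix(0, 4, 4, dimnames = list(labels, labels))
  W["a", "c"] <- W["c", "a"] <- 0.3
  W["a", "d"] <- W["d", "a"] <- -0.1
  W["a", "b"] <- W["b", "a"] <- 0.2
  as_pcor_network(W, c(a = "g1", b = "g1", c = "g2", d = "g2"))
}

# random positive-definite correlation matrix
rand_cor <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * p * 4), 4 * p, p)
    stats::cov2cor(crossprod(A) / (4 * p))
  })
}

# node_scores table of p independent continuous columns
indep_scores <- function(n, p = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p)
    colnames(m) <- paste0("v", seq_len(p))
    tbl <- tibble::as_tibble(as.data.frame(m))
    tbl <- dplyr::bind_cols(
      tibble::tibble(respondent_id = as.character(seq_len(n))), tbl
    )
    comm <- setNames(rep(c("g1", "g2"), length.out = p), colnames(m))
    bridgenet:::new_node_scores(tbl, comm)
  })
}

# partial correlation of nodes i and j given the rest, from the covariance:
# Schur-complement route, independent of the precision-matrix formula
pcor_oracle <- function(Sigma, i, j) {
  rest <- setdiff(seq_len(ncol(Sigma)), c(i, j))
  A <- c(i, j)
  cond <- Sigma[A, A] - Sigma[A, rest] %*% solve(Sigma[rest, rest], Sigma[rest, A])
  cond[1, 2] / sqrt(cond[1, 1] * cond[2, 2])
}

# strong 6-node two-community planted structure on a continuous latent scale:
# big enough partial correlations that EBIC selection recovers them at modest n
strong_spec <- function() {
  labels <- c("L1", "L2", "L3", "R1", "R2", "R3")
  P <- matrix(0, 6, 6, dimnames = list(labels, labels))
  set_edge <- function(a, b, w) {
    P[a, b] <<- w
    P[b, a] <<- w
  }
  set_edge("L1", "L2", 0.35); set_edge("L2", "L3", 0.3)
  set_edge("R1", "R2", 0.35); set_edge("R2", "R3", 0.3)
  set_edge("L1", "R1", 0.3); set_edge("L3", "R3", -0.2)
  make_true_network(
    pcor = P,
    communities = setNames(rep(c("left", "right"), each = 3), labels),
    targets = NULL
  )
}
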