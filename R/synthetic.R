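# run code with a temporary RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic Gaussian-CDF moment matching: choose (mu, sigma) of the latent
# scale so that discretizing N(mu, sigma^2) at the midpoints between adjacent
# codes reproduces the target mean/sd as closely as the grid allows. Returns
# thresholds on the standard-normal z scale.
calibrate_thresholds <- function(codes, target_mean, target_sd) {
  codes <- as.numeric(codes)
  stopifnot(length(codes) >= 2, all(diff(codes) > 0), target_sd > 0)
  bounds <- (codes[-1] + codes[-length(codes)]) / 2
  moments <- function(mu, sigma) {
    z <- (bounds - mu) / sigma
    p <- diff(c(0, pnorm(z), 1))
    m <- sum(codes * p)
    s <- sqrt(max(sum(codes^2 * p) - m^2, 0))
    c(m, s)
  }
  obj <- function(par) {
    if (par[2] <= 0) return(1e6)
    ms <- moments(par[1], par[2])
    (ms[1] - target_mean)^2 + (ms[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, target_sd), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1]; sigma <- fit$par[2]
  ach <- moments(mu, sigma)
  list(
    thresholds = (bounds - mu) / sigma,
    codes = codes,
    achieved_mean = ach[1],
    achieved_sd = ach[2]
  )
}

#' Planted two-community ground-truth network
#'
#' Builds the ground-truth partial-correlation structure that drives the
#' synthetic Likert cohort generator. The default preset mirrors the
#' published anxiety-IGD network: 5 anxiety nodes and 9 IGD nodes, a
#' cross-community block holding exactly the 23 printed edge weights (20
#' positive, 3 negative; the largest, 0.12, at A3-IGD5; designated bridge
#' nodes A2, A3 and IGD5), a sparse within-community backbone of constant
#' weight (drawn once with a fixed internal seed so the preset is fully
#' deterministic), and per-node Likert thresholds calibrated to the published
#' means and standard deviations.
#'
#' The implied precision matrix \eqn{K^* = I - P^*} is checked for positive
#' definiteness; if needed, all off-diagonals are shrunk by a common factor
#' (recorded on the object) and the exact implied partial correlations are
#' recomputed.
#'
#' @param pcor Optional custom planted partial-correlation matrix (symmetric,
#'   zero diagonal, entries in (-1, 1), labelled dimnames). Overrides the
#'   preset structure.
#' @param communities Named community vector; required with a custom `pcor`.
#' @param targets Per-node discretization targets: tibble with `node`,
#'   `mean`, `sd` (default: the published descriptives). Nodes absent from
#'   `targets` get standard-normal latent scores without discretization.
#' @param within_weight Weight of planted within-community edges
#'   (default 0.15).
#' @param within_density Fraction of within-community pairs that receive an
#'   edge (default 0.35).
#' @param backbone_seed Fixed seed for the within-community backbone draw
#'   (part of the preset definition, independent of simulation seeds).
#' @return An object of class `true_network`.
#' @export
#' @examples
#' spec <- make_true_network()
#' spec$bridge_nodes
make_true_network <- function(pcor = NULL, communities = NULL,
                              targets = published_descriptives(),
                              within_weight = 0.15, within_density = 0.35,
                              backbone_seed = 42) {
  if (is.null(pcor)) {
    desc <- published_descriptives()
    labels <- desc$node
    communities <- setNames(desc$community, desc$node)
    p <- length(labels)
    P <- matrix(0, p, p, dimnames = list(labels, labels))
    edges <- published_cross_edges()
    for (i in seq_len(nrow(edges))) {
      P[edges$node_a[i], edges$node_b[i]] <- edges$weight[i]
      P[edges$node_b[i], edges$node_a[i]] <- edges$weight[i]
    }
    # sparse within-community backbone, fixed draw
    with_local_seed(backbone_seed, {
      for (comm in unique(communities)) {
        members <- labels[communities == comm]
        pairs <- utils::combn(members, 2)
        k <- max(1L, round(within_density * ncol(pairs)))
        pick <- sample(ncol(pairs), k)
        for (j in pick) {
          a <- pairs[1, j]; b <- pairs[2, j]
          P[a, b] <- within_weight
          P[b, a] <- within_weight
        }
      }
    })
    bridge_nodes <- c("A2", "A3", "IGD5")
  } else {
    P <- as.matrix(pcor)
    labels <- colnames(P)
    if (is.null(labels)) abort("custom `pcor` needs labelled dimnames.")
    if (is.null(communities)) abort("custom `pcor` needs `communities`.")
    communities <- communities[labels]
    if (max(abs(P - t(P))) > 1e-12 || any(diag(P) != 0) || any(abs(P) >= 1)) {
      abort("custom `pcor` must be symmetric, zero-diagonal, entries in (-1, 1).")
    }
    bridge_nodes <- character(0)
  }
  p <- ncol(P)
  K <- diag(p) - P
  dimnames(K) <- dimnames(P)
  shrink <- 1
  while (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) <= 1e-6) {
    shrink <- shrink * 0.95
    if (shrink < 0.5) {
      abort("planted structure cannot be made positive definite by shrinkage factor >= 0.5.")
    }
    K <- diag(p) - shrink * P
    dimnames(K) <- dimnames(P)
  }
  P_implied <- precision_to_pcor(K)
  dimnames(P_implied) <- dimnames(P)
  Sigma <- stats::cov2cor(solve(K))
  dimnames(Sigma) <- dimnames(P)

  node_codes <- function(node) {
    if (startsWith(node, "A")) {
      sizes <- c(A1 = 4, A2 = 4, A3 = 3, A4 = 4, A5 = 4)
      k <- sizes[node]
      if (is.na(k)) k <- 4
      0:(3 * k)
    } else {
      1:5
    }
  }
  thresholds <- NULL
  if (!is.null(targets)) {
    targets <- tibble::as_tibble(targets)
    thresholds <- lapply(seq_len(nrow(targets)), function(i) {
      calibrate_thresholds(node_codes(targets$node[i]),
                           targets$mean[i], targets$sd[i])
    })
    names(thresholds) <- targets$node
  }
  structure(
    list(
      pcor = P_implied, precision = K, sigma = Sigma,
      labels = labels, communities = communities,
      bridge_nodes = bridge_nodes, targets = targets,
      thresholds = thresholds, shrink_factor = shrink
    ),
    class = "true_network"
  )
}

#' @export
print.true_network <- function(x, ...) {
  ut <- x$pcor[upper.tri(x$pcor)]
  cat(sprintf(
    "<true_network> %d nodes, %d planted edges (shrink factor %.3g)\n",
    length(x$labels), sum(ut != 0), x$shrink_factor
  ))
  invisible(x)
}

#' The planted truth as a `pcor_network`
#'
#' @param spec A `true_network`.
#' @return A `pcor_network` holding the exact planted partial correlations.
#' @export
true_pcor_network <- function(spec) {
  as_pcor_network(spec$pcor, spec$communities)
}

#' Simulate a Likert questionnaire cohort from a planted network
#'
#' Draws latent multivariate-normal scores with the correlation structure
#' implied by the planted precision matrix, then discretizes each node onto
#' its Likert code range through the calibrated thresholds, so that the
#' discrete node means and standard deviations match the targets as closely
#' as discretization allows. `level = "item"` additionally expands each
#' multi-item dimension into correlated item responses (loading 0.7 on the
#' node latent), for exercising the item-level scoring path.
#'
#' @param spec A `true_network` from [make_true_network()].
#' @param n Cohort size.
#' @param seed Reproducibility seed (required; the caller's RNG state is left
#'   untouched).
#' @param level `"node"` (default) returns the 14-column node-score table the
#'   network is estimated on; `"item"` returns raw item responses compatible
#'   with [load_item_responses()] and [default_scale_definitions()].
#' @param loading Item-on-node latent loading for `level = "item"`.
#' @return For `"node"`: a `node_scores` tibble. For `"item"`: a tibble of
#'   item columns.
#' @export
#' @examples
#' spec <- make_true_network()
#' scores <- simulate_cohort(spec, n = 200, seed = 11)
#' descriptive_stats(scores)
simulate_cohort <- function(spec, n, seed, level = c("node", "item"),
                            loading = 0.7) {
  stopifnot(inherits(spec, "true_network"), n >= 1)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  level <- match.arg(level)
  p <- length(spec$labels)
  discretize <- function(z, cal) {
    if (any(diff(cal$thresholds) <= 0)) {
      abort("Likert thresholds must be strictly increasing.")
    }
    cal$codes[1L + findInterval(z, cal$thresholds)]
  }
  with_local_seed(seed, {
    Z <- matrix(rnorm(n * p), n, p) %*% chol(spec$sigma)
    colnames(Z) <- spec$labels
    if (level == "node") {
      cols <- list(respondent_id = as.character(seq_len(n)))
      for (j in spec$labels) {
        cal <- spec$thresholds[[j]]
        cols[[j]] <- if (is.null(cal)) Z[, j] else
          as.numeric(discretize(Z[, j], cal))
      }
      new_node_scores(tibble::as_tibble(cols), spec$communities)
    } else {
      defs <- default_scale_definitions()
      cols <- list(respondent_id = as.character(seq_len(n)))
      for (d in defs) {
        for (i in seq_along(d$dimensions)) {
          node <- paste0(d$node_prefix, i)
          items <- d$dimensions[[i]]
          k <- length(items)
          tgt <- spec$targets[spec$targets$node == node, ]
          for (it in items) {
            if (k == 1) {
              cal <- spec$thresholds[[node]]
              cols[[it]] <- as.integer(discretize(Z[, node], cal))
            } else {
              u <- loading * Z[, node] +
                sqrt(1 - loading^2) * rnorm(n)
              cal <- calibrate_thresholds(
                d$level_codes,
                target_mean = tgt$mean / k,
                target_sd = max(tgt$sd / sqrt(k), 0.4)
              )
              cols[[it]] <- as.integer(discretize(u, cal))
            }
          }
        }
      }
      tibble::as_tibble(cols)
    }
  })
}

#' Recovery metrics of an estimated network against the planted truth
#'
#' Compares the support and weights of an estimated partial-correlation
#' network with the planted structure: edge-set sensitivity and specificity,
#' mean absolute error over the truly nonzero edges, and the Spearman rank
#' correlation between the true and estimated bridge-expected-influence
#' vectors.
#'
#' @param spec A `true_network`.
#' @param net An estimated `pcor_network` over the same node labels.
#' @return One-row tibble: `sensitivity`, `specificity`, `mae_nonzero`,
#'   `bei_rank_cor`, `bridges_in_top3`.
#' @export
recovery_metrics <- function(spec, net) {
  stopifnot(inherits(spec, "true_network"), inherits(net, "pcor_network"))
  if (!identical(sort(spec$labels), sort(net$labels))) {
    abort("node labels of truth and estimate do not match.")
  }
  Pt <- spec$pcor[net$labels, net$labels]
  Pe <- net$weights
  ut <- upper.tri(Pt)
  truth_nz <- Pt[ut] != 0
  est_nz <- Pe[ut] != 0
  sens <- if (any(truth_nz)) mean(est_nz[truth_nz]) else NA_real_
  spec_ <- if (any(!truth_nz)) mean(!est_nz[!truth_nz]) else NA_real_
  mae <- if (any(truth_nz)) {
    mean(abs(Pe[ut][truth_nz] - Pt[ut][truth_nz]))
  } else NA_real_
  bei_true <- bridge_expected_influence(true_pcor_network(spec))
  bei_est <- bridge_expected_influence(net)
  ord <- match(bei_true$node, bei_est$node)
  rc <- suppressWarnings(
    cor(bei_true$bei, bei_est$bei[ord], method = "spearman")
  )
  top3 <- head(bei_est$node[order(-bei_est$bei)], 3)
  tibble::tibble(
    sensitivity = sens,
    specificity = spec_,
    mae_nonzero = mae,
    bei_rank_cor = rc,
    bridges_in_top3 = if (length(spec$bridge_nodes) > 0) {
      all(spec$bridge_nodes %in% top3)
    } else NA
  )
}
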