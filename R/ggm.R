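#' Marginal correlation matrix of the node scores
#'
#' Computes the Pearson (default) or Spearman correlation matrix that feeds
#' the graphical lasso. If numerical rank-deficiency makes the smallest
#' eigenvalue non-positive, the matrix is repaired to the nearest
#' positive-definite correlation matrix by eigenvalue clipping (at 1e-8) with
#' a warning; the method and any repair are recorded on the result.
#'
#' @param scores A `node_scores` tibble.
#' @param method `"pearson"` (default) or `"spearman"`. Polychoric
#'   correlations are deliberately out of scope.
#' @return An object of class `correlation_matrix`: list with `values`
#'   (symmetric, unit diagonal), `labels`, `method`, `n`, `repaired`.
#' @export
sample_correlation <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- score_matrix(scores)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf(
      "constant node column(s): %s",
      paste(colnames(m)[sds == 0], collapse = ", ")
    ))
  }
  R <- cor(m, method = method)
  R <- (R + t(R)) / 2
  diag(R) <- 1
  repaired <- FALSE
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) <= 1e-10) {
    warn("sample correlation matrix not positive definite; applying nearest-PD repair (eigenvalue clipping at 1e-8).")
    vals <- pmax(ev$values, 1e-8)
    nm <- dimnames(R)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
    diag(R) <- 1
    dimnames(R) <- nm
    repaired <- TRUE
  }
  structure(
    list(values = R, labels = colnames(m), method = method, n = nrow(m),
         repaired = repaired),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d nodes, %s, n = %d%s\n",
              length(x$labels), x$method, x$n,
              if (x$repaired) " (PD-repaired)" else ""))
  invisible(x)
}

cor_values <- function(S) {
  if (inherits(S, "correlation_matrix")) S$values else as.matrix(S)
}

#' Penalty grid for the graphical-lasso path
#'
#' Log-spaced decreasing sequence from \eqn{\lambda_{max}} (the largest
#' absolute off-diagonal marginal correlation, above which the estimated
#' graph is empty) down to `min_ratio` times it.
#'
#' @param S A `correlation_matrix` or plain symmetric matrix.
#' @param n_lambda Number of grid points (default 100).
#' @param min_ratio Ratio of the smallest to the largest penalty
#'   (default 0.01).
#' @return Strictly decreasing numeric vector of penalties.
#' @export
lambda_path_grid <- function(S, n_lambda = 100, min_ratio = 0.01) {
  stopifnot(n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  v <- cor_values(S)
  lambda_max <- max(abs(v[upper.tri(v)]))
  if (lambda_max == 0) {
    warn("all off-diagonal correlations are zero; degenerate single-point path at lambda = 0.")
    return(0)
  }
  exp(seq(log(lambda_max), log(min_ratio * lambda_max), length.out = n_lambda))
}

#' Graphical lasso at a single penalty
#'
#' L1-penalized maximum-likelihood estimate of the precision matrix: the
#' maximizer of \eqn{\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j}
#' |K_{ij}|} (diagonal unpenalized), computed by block coordinate descent
#' with a relative duality-gap stopping rule.
#'
#' @param S A `correlation_matrix` or symmetric positive-definite matrix with
#'   unit diagonal.
#' @param lambda Non-negative penalty.
#' @param tol Relative duality-gap tolerance (default 1e-6).
#' @param maxit Sweep cap per penalty (default 1000).
#' @return An object of class `precision_matrix`: list with `values`
#'   (symmetric positive-definite K), `lambda`, `iterations`, `gap`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 1000) {
  stopifnot(lambda >= 0)
  v <- cor_values(S)
  fit <- .glasso_cpp(v, lambda, tol, maxit, NULL)
  if (!fit$converged) {
    abort(sprintf(
      "graphical lasso did not converge at lambda = %.6g (duality gap %.3g after %d sweeps).",
      lambda, fit$gap, fit$iterations
    ))
  }
  K <- fit$theta
  dimnames(K) <- dimnames(v)
  structure(
    list(values = K, lambda = lambda, iterations = fit$iterations,
         gap = fit$gap),
    class = "precision_matrix"
  )
}

precision_values <- function(K) {
  if (inherits(K, "precision_matrix")) K$values else as.matrix(K)
}

#' Gaussian log-likelihood of a precision matrix
#'
#' \eqn{L = (n/2)(\log\det K - \mathrm{tr}(SK))}, the profiled multivariate
#' normal log-likelihood (up to an additive constant) used by the EBIC.
#'
#' @param K A `precision_matrix` or positive-definite matrix.
#' @param S The sample correlation (or covariance) matrix.
#' @param n Sample size.
#' @return Finite scalar log-likelihood.
#' @export
gaussian_loglik <- function(K, S, n) {
  Km <- precision_values(K)
  Sm <- cor_values(S)
  ld <- determinant(Km, logarithm = TRUE)
  if (ld$sign <= 0) abort("precision matrix is not positive definite.")
  (n / 2) * (as.numeric(ld$modulus) - sum(Sm * Km))
}

#' Extended Bayesian information criterion of a fitted precision matrix
#'
#' \eqn{\mathrm{EBIC} = -2L + E \log n + 4 \gamma E \log p}, with \eqn{E}
#' the number of nonzero off-diagonal edge pairs. `gamma = 0` reduces to the
#' ordinary BIC; larger values prefer sparser graphs.
#'
#' @inheritParams gaussian_loglik
#' @param gamma EBIC hyperparameter, non-negative (0.5 balances sensitivity
#'   against specificity).
#' @return Finite scalar; lower is better.
#' @export
ebic_score <- function(K, S, n, gamma = 0.5) {
  stopifnot(gamma >= 0)
  Km <- precision_values(K)
  p <- ncol(Km)
  E <- sum(Km[upper.tri(Km)] != 0)
  -2 * gaussian_loglik(Km, S, n) + E * log(n) + 4 * gamma * E * log(p)
}

#' Convert a precision matrix to partial correlations
#'
#' \eqn{\rho_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}} with the diagonal set to
#' zero: the edge weights of the Gaussian graphical model.
#'
#' @param K A `precision_matrix` or positive-definite matrix.
#' @return Symmetric matrix of partial correlations, zero diagonal.
#' @export
precision_to_pcor <- function(K) {
  Km <- precision_values(K)
  d <- sqrt(diag(Km))
  P <- -Km / tcrossprod(d)
  diag(P) <- 0
  (P + t(P)) / 2
}

#' Estimate the regularized partial-correlation network
#'
#' The full estimation pipeline: marginal correlations, graphical-lasso path
#' over a decreasing penalty grid (warm-started), EBIC model selection
#' (ties broken toward the sparser model, i.e. the larger penalty), and
#' conversion of the selected precision matrix to partial-correlation edge
#' weights.
#'
#' @param scores A `node_scores` tibble.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param method Marginal correlation method, `"pearson"` or `"spearman"`.
#' @param n_lambda,min_ratio Penalty-grid controls (see [lambda_path_grid()]).
#' @param tol,maxit Convergence controls (see [glasso_fit()]).
#' @return An object of class `pcor_network`: list with `weights` (symmetric,
#'   zero diagonal), `labels`, `communities`, `n`, `lambda` (selected),
#'   `gamma`, `method`, and the `path` diagnostics (lambdas, EBIC scores,
#'   edge counts).
#' @export
#' @examples
#' spec <- make_true_network()
#' scores <- simulate_cohort(spec, n = 400, seed = 7)
#' net <- estimate_network(scores)
#' glance(net)
estimate_network <- function(scores, gamma = 0.5,
                             method = c("pearson", "spearman"),
                             n_lambda = 100, min_ratio = 0.01,
                             tol = 1e-6, maxit = 1000) {
  method <- match.arg(method)
  S <- sample_correlation(scores, method = method)
  n <- S$n
  lambdas <- lambda_path_grid(S, n_lambda = n_lambda, min_ratio = min_ratio)
  path <- .glasso_path_cpp(S$values, lambdas, tol, maxit)
  if (!all(path$converged)) {
    bad <- which(!path$converged)[1]
    abort(sprintf(
      "graphical lasso did not converge at lambda = %.6g (duality gap %.3g).",
      lambdas[bad], path$gaps[bad]
    ))
  }
  ebic <- vapply(seq_along(lambdas), function(i) {
    ebic_score(path$thetas[[i]], S, n, gamma = gamma)
  }, numeric(1))
  edge_counts <- vapply(path$thetas, function(Th) {
    sum(Th[upper.tri(Th)] != 0)
  }, numeric(1))
  best <- which.min(ebic) # first minimum = largest lambda among ties
  K <- path$thetas[[best]]
  W <- precision_to_pcor(K)
  dimnames(W) <- list(S$labels, S$labels)
  new_pcor_network(
    weights = W,
    communities = node_communities(scores),
    n = n,
    lambda = lambdas[best],
    gamma = gamma,
    method = method,
    path = tibble::tibble(lambda = lambdas, ebic = ebic,
                          n_edges = edge_counts)
  )
}

new_pcor_network <- function(weights, communities, n = NA_integer_,
                             lambda = NA_real_, gamma = NA_real_,
                             method = NA_character_, path = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  labels <- colnames(weights)
  if (is.null(labels)) abort("weight matrix must have node labels as dimnames.")
  if (max(abs(weights - t(weights))) > 1e-10) {
    abort("weight matrix must be symmetric.")
  }
  if (any(diag(weights) != 0)) abort("weight matrix must have a zero diagonal.")
  if (any(abs(weights) >= 1)) abort("edge weights must lie strictly in (-1, 1).")
  if (is.null(names(communities)) || !setequal(names(communities), labels)) {
    abort("`communities` must be a named vector covering every node label.")
  }
  structure(
    list(weights = weights, labels = labels,
         communities = communities[labels], n = n, lambda = lambda,
         gamma = gamma, method = method, path = path),
    class = "pcor_network"
  )
}

#' Construct a partial-correlation network from a known weight matrix
#'
#' Wraps an already-known symmetric edge-weight matrix (for example the edge
#' list printed in a publication, or a planted ground-truth structure) in the
#' same `pcor_network` container that [estimate_network()] returns, so the
#' bridge-centrality and reporting tools apply to it unchanged.
#'
#' @param weights Symmetric numeric matrix, zero diagonal, entries in
#'   (-1, 1), with node labels as dimnames.
#' @param communities Named character vector mapping every node label to its
#'   community.
#' @param n Sample size behind the weights, if known.
#' @return A `pcor_network` object.
#' @export
as_pcor_network <- function(weights, communities, n = NA_integer_) {
  new_pcor_network(weights, communities, n = n)
}

#' @export
print.pcor_network <- function(x, ...) {
  ne <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf(
    "<pcor_network> %d nodes (%s), %d edges%s\n",
    length(x$labels),
    paste(sprintf("%s: %d", names(table(x$communities)),
                  as.integer(table(x$communities))), collapse = ", "),
    ne,
    if (!is.na(x$lambda)) sprintf(", lambda = %.4g (gamma = %g, n = %d)",
                                  x$lambda, x$gamma, x$n) else ""
  ))
  invisible(x)
}

#' @describeIn estimate_network One row per (unordered) node pair with a
#'   nonzero edge: `node_a`, `node_b`, `weight`, `is_cross_community`.
#' @param x A `pcor_network`.
#' @param all_pairs Keep zero-weight pairs too (default `FALSE`).
#' @param ... Unused.
#' @export
tidy.pcor_network <- function(x, all_pairs = FALSE, ...) {
  p <- length(x$labels)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  out <- tibble::tibble(
    node_a = x$labels[idx[, 1]],
    node_b = x$labels[idx[, 2]],
    weight = x$weights[idx],
    is_cross_community =
      x$communities[x$labels[idx[, 1]]] != x$communities[x$labels[idx[, 2]]]
  )
  if (!all_pairs) out <- dplyr::filter(out, .data$weight != 0)
  dplyr::arrange(out, dplyr::desc(abs(.data$weight)))
}

#' @describeIn estimate_network One-row summary: node/edge counts, selected
#'   penalty, sparsity.
#' @export
glance.pcor_network <- function(x, ...) {
  ut <- x$weights[upper.tri(x$weights)]
  tibble::tibble(
    n_nodes = length(x$labels),
    n_edges = sum(ut != 0),
    n_possible = length(ut),
    sparsity = 1 - sum(ut != 0) / length(ut),
    lambda = x$lambda,
    gamma = x$gamma,
    n = x$n,
    method = x$method
  )
}
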