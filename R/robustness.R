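edge_ids <- function(labels) {
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  paste0(labels[idx[, 1]], "--", labels[idx[, 2]])
}

upper_weights <- function(net) {
  net$weights[upper.tri(net$weights)]
}

#' Nonparametric bootstrap of edge weights
#'
#' Resamples respondents with replacement, re-runs the whole estimation
#' pipeline on every resample, and summarizes each edge weight by its
#' percentile bootstrap confidence interval (2.5th/97.5th replicate
#' quantiles at the default 95% level). Replicates on which estimation fails
#' are dropped and counted; more than 5% failures aborts.
#'
#' @param scores A `node_scores` tibble.
#' @param B Number of bootstrap replicates (1000 in the published protocol;
#'   reduce for quick checks).
#' @param gamma EBIC hyperparameter passed to [estimate_network()].
#' @param seed Required reproducibility seed.
#' @param conf Confidence level (default 0.95).
#' @param ... Further arguments to [estimate_network()].
#' @return An object of class `edge_bootstrap` with the replicate matrix, the
#'   full-sample network, and per-edge CIs (see [tidy()]).
#' @export
#' @examples
#' spec <- make_true_network()
#' scores <- simulate_cohort(spec, n = 300, seed = 5)
#' boot <- bootstrap_edge_ci(scores, B = 25, seed = 9)
#' tidy(boot)
bootstrap_edge_ci <- function(scores, B = 1000, gamma = 0.5, seed,
                              conf = 0.95, ...) {
  stopifnot(B >= 2)
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  net <- estimate_network(scores, gamma = gamma, ...)
  m <- score_matrix(scores)
  n <- nrow(m)
  ids <- edge_ids(net$labels)
  comm <- net$communities
  reps <- matrix(NA_real_, B, length(ids), dimnames = list(NULL, ids))
  n_failed <- 0
  with_local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      sub <- new_node_scores(
        tibble::as_tibble(as.data.frame(scores)[idx, , drop = FALSE]), comm
      )
      fit <- tryCatch(
        estimate_network(sub, gamma = gamma, ...),
        error = function(e) NULL
      )
      if (is.null(fit)) n_failed <- n_failed + 1
      else reps[b, ] <- upper_weights(fit)
    }
  })
  if (n_failed / B > 0.05) {
    abort(sprintf("%d of %d bootstrap replicates failed (> 5%%).", n_failed, B))
  }
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  alpha <- 1 - conf
  ci <- apply(reps, 2, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  idx_ut <- which(upper.tri(net$weights), arr.ind = TRUE)
  edge_info <- tibble::tibble(
    edge = ids,
    node_a = net$labels[idx_ut[, 1]],
    node_b = net$labels[idx_ut[, 2]],
    is_cross_community =
      comm[net$labels[idx_ut[, 1]]] != comm[net$labels[idx_ut[, 2]]]
  )
  structure(
    list(
      replicates = reps, edge_info = edge_info,
      sample_estimate = setNames(upper_weights(net), ids),
      lower = setNames(ci[1, ], ids), upper = setNames(ci[2, ], ids),
      B = nrow(reps), B_requested = B, n_failed = n_failed,
      conf = conf, seed = seed, net = net
    ),
    class = "edge_bootstrap"
  )
}

#' @export
print.edge_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<edge_bootstrap> %d replicates (%d failed), %d edges, %.0f%% percentile CIs\n",
    x$B, x$n_failed, ncol(x$replicates), 100 * x$conf
  ))
  invisible(x)
}

#' @export
tidy.edge_bootstrap <- function(x, ...) {
  dplyr::mutate(
    x$edge_info,
    estimate = unname(x$sample_estimate),
    boot_mean = unname(colMeans(x$replicates)),
    lower = unname(x$lower),
    upper = unname(x$upper)
  )
}

#' @export
glance.edge_bootstrap <- function(x, ...) {
  tibble::tibble(
    B = x$B, n_failed = x$n_failed, conf = x$conf,
    median_ci_width = stats::median(x$upper - x$lower)
  )
}

#' Case-dropping bootstrap of bridge expected influence
#'
#' For each proportion on the grid, repeatedly drops that fraction of
#' respondents uniformly at random (without replacement), re-estimates the
#' network on the retained subsample, recomputes BEI, and records the
#' correlation between the subsample and full-sample BEI vectors. This is
#' the stability experiment the CS-coefficient summarizes.
#'
#' @param scores A `node_scores` tibble.
#' @param grid Strictly increasing drop proportions in (0, 0.95); default
#'   0.05 to 0.75 in steps of 0.05.
#' @param B Replicates per proportion.
#' @param seed Required reproducibility seed.
#' @param gamma EBIC hyperparameter.
#' @param cor_method Correlation between BEI vectors: `"pearson"` (default)
#'   or `"spearman"`.
#' @param ... Further arguments to [estimate_network()].
#' @return An object of class `case_drop`: replicate correlations per
#'   proportion plus the full-sample BEI vector.
#' @export
case_drop_bootstrap <- function(scores, grid = seq(0.05, 0.75, by = 0.05),
                                B = 1000, seed, gamma = 0.5,
                                cor_method = c("pearson", "spearman"), ...) {
  stopifnot(B >= 2, all(grid > 0), all(grid < 0.95), all(diff(grid) > 0))
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  cor_method <- match.arg(cor_method)
  net <- estimate_network(scores, gamma = gamma, ...)
  full_bei <- bridge_expected_influence(net)
  p <- length(net$labels)
  n <- nrow(scores)
  comm <- net$communities
  rows <- list()
  degenerate <- FALSE
  with_local_seed(seed, {
    for (q in grid) {
      n_keep <- n - floor(q * n)
      if (n_keep < p + 1) {
        warn(sprintf(
          "drop proportion %.2f leaves %d < %d cases; skipped.", q, n_keep, p + 1
        ))
        next
      }
      cors <- numeric(B)
      for (b in seq_len(B)) {
        idx <- sample.int(n, n_keep)
        sub <- new_node_scores(
          tibble::as_tibble(as.data.frame(scores)[idx, , drop = FALSE]), comm
        )
        cors[b] <- tryCatch({
          fit <- estimate_network(sub, gamma = gamma, ...)
          bei <- bridge_expected_influence(fit)$bei
          if (sd(bei) == 0 || sd(full_bei$bei) == 0) {
            degenerate <- TRUE
            NA_real_
          } else {
            cor(full_bei$bei, bei, method = cor_method)
          }
        }, error = function(e) NA_real_)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        proportion = q, replicate = seq_len(B), correlation = cors
      )
    }
  })
  if (degenerate) {
    warn("constant BEI vector in at least one replicate; correlation recorded as missing.")
  }
  if (length(rows) == 0) abort("no usable drop proportion on the grid.")
  structure(
    list(
      replicates = dplyr::bind_rows(rows),
      full_bei = setNames(full_bei$bei, full_bei$node),
      grid = grid, B = B, seed = seed, cor_method = cor_method, n = n
    ),
    class = "case_drop"
  )
}

#' @export
print.case_drop <- function(x, ...) {
  cat(sprintf(
    "<case_drop> %d proportions x %d replicates (%s correlation, n = %d)\n",
    length(unique(x$replicates$proportion)), x$B, x$cor_method, x$n
  ))
  invisible(x)
}

#' @export
tidy.case_drop <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$replicates, .data$proportion),
    mean_cor = mean(.data$correlation, na.rm = TRUE),
    median_cor = stats::median(.data$correlation, na.rm = TRUE),
    q025 = quantile(.data$correlation, 0.025, na.rm = TRUE, names = FALSE),
    q975 = quantile(.data$correlation, 0.975, na.rm = TRUE, names = FALSE),
    n_missing = sum(is.na(.data$correlation)),
    .groups = "drop"
  )
}

#' Correlation-stability coefficient
#'
#' The largest drop proportion \eqn{q} on the grid such that, at \eqn{q} and
#' at every smaller grid proportion, at least `prob` of the replicate
#' correlations with the full-sample statistic are at or above
#' `cor_threshold`; 0 when the condition fails already at the smallest
#' proportion. Requiring the condition at all smaller proportions guards
#' against spurious non-monotone maxima. Values above 0.5 are conventionally
#' read as ideal stability, values above 0.25 as acceptable.
#'
#' @param result A `case_drop` object.
#' @param cor_threshold Correlation threshold (default 0.7).
#' @param prob Required fraction of replicates meeting the threshold
#'   (default 0.95). Missing correlations are excluded.
#' @return An object of class `cs_coefficient` with fields `value`,
#'   `cor_threshold`, `prob` and the per-proportion pass table.
#' @export
cs_coefficient <- function(result, cor_threshold = 0.7, prob = 0.95) {
  stopifnot(inherits(result, "case_drop"))
  tab <- dplyr::summarise(
    dplyr::group_by(result$replicates, .data$proportion),
    pass_rate = mean(.data$correlation >= cor_threshold, na.rm = TRUE),
    .groups = "drop"
  )
  tab <- dplyr::arrange(tab, .data$proportion)
  tab$ok <- !is.nan(tab$pass_rate) & tab$pass_rate >= prob
  value <- 0
  for (i in seq_len(nrow(tab))) {
    if (tab$ok[i]) value <- tab$proportion[i] else break
  }
  structure(
    list(value = value, cor_threshold = cor_threshold, prob = prob,
         table = tab),
    class = "cs_coefficient"
  )
}

#' @export
print.cs_coefficient <- function(x, ...) {
  cat(sprintf(
    "<cs_coefficient> CS(cor = %.2f, prob = %.2f) = %.2f %s\n",
    x$cor_threshold, x$prob, x$value,
    if (x$value > 0.5) "(ideal stability)"
    else if (x$value > 0.25) "(acceptable stability)" else "(unstable)"
  ))
  invisible(x)
}

#' Bootstrapped difference tests for edges or bridge influence
#'
#' For every pair of edges (or of node BEI values), forms the percentile
#' bootstrap confidence interval of the replicate-wise difference and flags
#' the pair as significantly different when that interval excludes zero. No
#' multiplicity correction is applied, matching the conventional reporting of
#' these tests; interpret the flags accordingly.
#'
#' @param boot An `edge_bootstrap` object.
#' @param what `"edge"` compares edge weights (restricted to edges nonzero in
#'   the full-sample network); `"bei"` compares node bridge expected
#'   influence, computed from the same replicates.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `difference_test`: tidy pair table plus the
#'   symmetric logical flag matrix.
#' @export
difference_tests <- function(boot, what = c("edge", "bei"), alpha = 0.05) {
  stopifnot(inherits(boot, "edge_bootstrap"))
  what <- match.arg(what)
  if (what == "edge") {
    keep <- boot$sample_estimate != 0
    reps <- boot$replicates[, keep, drop = FALSE]
  } else {
    labels <- boot$net$labels
    comm <- boot$net$communities
    idx <- which(upper.tri(boot$net$weights), arr.ind = TRUE)
    M <- matrix(0, length(labels), nrow(idx),
                dimnames = list(labels, colnames(boot$replicates)))
    for (e in seq_len(nrow(idx))) {
      a <- idx[e, 1]; b <- idx[e, 2]
      if (comm[labels[a]] != comm[labels[b]]) {
        M[a, e] <- 1
        M[b, e] <- 1
      }
    }
    reps <- boot$replicates %*% t(M)
  }
  nm <- colnames(reps)
  k <- length(nm)
  flags <- matrix(NA, k, k, dimnames = list(nm, nm))
  pairs <- list()
  if (k >= 2) {
    cmb <- utils::combn(k, 2)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]; b <- cmb[2, j]
      d <- reps[, a] - reps[, b]
      ci <- quantile(d, probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
      different <- ci[1] > 0 || ci[2] < 0
      flags[a, b] <- different
      flags[b, a] <- different
      pairs[[j]] <- tibble::tibble(
        a = nm[a], b = nm[b], lower = ci[1], upper = ci[2],
        different = different
      )
    }
  }
  structure(
    list(
      what = what, alpha = alpha, flags = flags,
      pairs = if (length(pairs)) dplyr::bind_rows(pairs) else
        tibble::tibble(a = character(), b = character(),
                       lower = numeric(), upper = numeric(),
                       different = logical()),
      note = "percentile bootstrap differences without multiplicity correction"
    ),
    class = "difference_test"
  )
}

#' @export
print.difference_test <- function(x, ...) {
  cat(sprintf(
    "<difference_test> %s pairs: %d of %d significantly different at alpha = %g\n  (%s)\n",
    x$what, sum(x$pairs$different), nrow(x$pairs), x$alpha, x$note
  ))
  invisible(x)
}

#' @export
tidy.difference_test <- function(x, ...) x$pairs
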