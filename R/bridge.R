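#' Bridge expected influence of every node
#'
#' The bridge expected influence (BEI) of a node is the signed sum of the
#' weights of its edges to all nodes belonging to other communities: a one-step
#' unnormalized index of how strongly a node connects its community to the
#' rest of the network. Summed over all nodes, BEI equals twice the total
#' cross-community edge weight.
#'
#' @param net A `pcor_network`.
#' @return A `bridge_table` tibble: `node`, `community`, `bei`, and
#'   `percentile_rank` (the empirical percentile of the node's BEI among all
#'   nodes, linear-interpolation definition).
#' @export
#' @examples
#' net <- published_edge_network()
#' bridge_expected_influence(net)
bridge_expected_influence <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  comm <- net$communities
  if (anyNA(comm)) abort("every node must be assigned to a community.")
  W <- net$weights
  cross <- outer(comm, comm, `!=`)
  bei <- rowSums(W * cross)
  out <- tibble::tibble(
    node = net$labels,
    community = unname(comm),
    bei = unname(bei),
    percentile_rank = 100 * vapply(
      bei, function(b) mean(bei <= b), numeric(1)
    )
  )
  class(out) <- c("bridge_table", class(out))
  out
}

#' Cross-community edges of a network
#'
#' Lists every strictly nonzero edge joining two different communities,
#' sorted by absolute weight (descending). The counts and the positive share
#' (percentage of listed edges with positive weight; `NA` when there are no
#' cross-community edges) are available through [glance()].
#'
#' @param net A `pcor_network`.
#' @return A `cross_edges` tibble: `node_a`, `node_b`, `weight`.
#' @export
#' @examples
#' glance(cross_community_edges(published_edge_network()))
cross_community_edges <- function(net) {
  stopifnot(inherits(net, "pcor_network"))
  edges <- tidy(net, all_pairs = FALSE)
  edges <- dplyr::filter(edges, .data$is_cross_community)
  edges <- dplyr::select(edges, -"is_cross_community")
  sizes <- table(net$communities)
  max_possible <- if (length(sizes) == 2) {
    as.integer(sizes[1]) * as.integer(sizes[2])
  } else {
    tot <- sum(sizes)
    as.integer((tot^2 - sum(sizes^2)) / 2)
  }
  structure(
    edges,
    counts = list(
      total = nrow(edges),
      positive = sum(edges$weight > 0),
      negative = sum(edges$weight < 0),
      positive_share = if (nrow(edges) == 0) NA_real_ else
        100 * sum(edges$weight > 0) / nrow(edges),
      max_possible = max_possible
    ),
    class = c("cross_edges", class(edges))
  )
}

#' @export
glance.cross_edges <- function(x, ...) {
  cts <- attr(x, "counts")
  tibble::tibble(
    total = cts$total,
    positive = cts$positive,
    negative = cts$negative,
    positive_share = cts$positive_share,
    max_possible = cts$max_possible
  )
}

#' Select bridge nodes by BEI percentile
#'
#' Nodes whose BEI is at or above the empirical `percentile` of all node BEI
#' values (linear-interpolation quantile, the R default type 7). With 14
#' distinct BEI values and the 80th percentile this selects the top three
#' nodes; when all values tie, every node is selected.
#'
#' @param table A `bridge_table` from [bridge_expected_influence()].
#' @param percentile Cut point in (0, 100), default 80.
#' @param type Quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation).
#' @return Character vector of selected node labels, ordered by decreasing
#'   BEI.
#' @export
select_bridge_nodes <- function(table, percentile = 80, type = 7) {
  stopifnot(percentile > 0, percentile < 100)
  thr <- quantile(table$bei, probs = percentile / 100, type = type,
                  names = FALSE)
  sel <- dplyr::filter(table, .data$bei >= thr)
  sel <- dplyr::arrange(sel, dplyr::desc(.data$bei))
  sel$node
}
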