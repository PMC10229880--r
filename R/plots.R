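#' Plot a partial-correlation network
#'
#' Force-directed node-link diagram in the conventional style: edge color
#' encodes the sign of the partial correlation (blue positive, red negative),
#' edge width and opacity its magnitude, node color the community.
#'
#' @param object A `pcor_network`.
#' @param layout Optional `network_layout`; computed with `seed` if missing.
#' @param seed Layout seed used when `layout` is missing.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcor_network <- function(object, layout = NULL, seed = 1, ...) {
  if (is.null(layout)) {
    layout <- fruchterman_reingold(object, seed = seed)
  }
  edges <- tidy(object)
  edges <- dplyr::left_join(
    edges, dplyr::rename(layout, xa = "x", ya = "y"),
    by = c(node_a = "node")
  )
  edges <- dplyr::left_join(
    edges, dplyr::rename(layout, xb = "x", yb = "y"),
    by = c(node_b = "node")
  )
  nodes <- dplyr::mutate(
    layout, community = unname(object$communities[.data$node])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb,
                   color = .data$weight > 0,
                   linewidth = abs(.data$weight),
                   alpha = abs(.data$weight))
    ) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "positive", `FALSE` = "negative"),
      name = "edge sign"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_alpha(range = c(0.3, 1), guide = "none") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$community),
      shape = 21, size = 9, color = "grey20"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node), size = 2.6
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "community")
}

#' Plot bridge expected influence per node
#'
#' @param object A `bridge_table`.
#' @param percentile Reference percentile line (default 80).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bridge_table <- function(object, percentile = 80, ...) {
  thr <- quantile(object$bei, percentile / 100, names = FALSE)
  dat <- dplyr::mutate(object,
                       node = factor(.data$node,
                                     levels = object$node[order(object$bei)]))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bei, y = .data$node,
                                    fill = .data$community)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = 2, color = "grey40") +
    ggplot2::labs(x = "bridge expected influence", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot case-dropping stability of bridge expected influence
#'
#' Mean replicate correlation with the full-sample BEI vector against the
#' drop proportion, with a 95% replicate band and the conventional 0.7
#' correlation reference line.
#'
#' @param object A `case_drop` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_drop <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$proportion, y = .data$mean_cor)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q025, ymax = .data$q975),
                         fill = "grey80") +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.7, linetype = 2, color = "grey40") +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full-sample BEI") +
    ggplot2::theme_minimal()
}

#' Plot bootstrapped edge-weight confidence intervals
#'
#' Edges ordered by the full-sample estimate, with the percentile bootstrap
#' interval and the bootstrap mean.
#'
#' @param object An `edge_bootstrap` result.
#' @param nonzero_only Show only edges nonzero in the full-sample network
#'   (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_bootstrap <- function(object, nonzero_only = TRUE, ...) {
  dat <- tidy(object)
  if (nonzero_only) dat <- dplyr::filter(dat, .data$estimate != 0)
  dat <- dplyr::mutate(dat,
                       edge = factor(.data$edge,
                                     levels = dat$edge[order(dat$estimate)]))
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$edge)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = .data$lower,
                                         xmax = .data$upper),
                            color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), color = "#b2182b",
                        size = 1) +
    ggplot2::geom_point(ggplot2::aes(x = .data$boot_mean), color = "grey30",
                        size = 0.7) +
    ggplot2::labs(x = "edge weight", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}
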