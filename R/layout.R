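#' Force-directed network layout
#'
#' Fruchterman-Reingold layout with the absolute edge weight as the
#' attraction multiplier (edge sign is conventionally encoded by color, not
#' geometry), rescaled to the unit square. Deterministic given
#' `(network, seed, iterations)`; the caller's RNG state is untouched.
#'
#' @param net A `pcor_network`.
#' @param iterations Number of layout iterations (default 500).
#' @param seed Required layout seed.
#' @return A `network_layout` tibble: `node`, `x`, `y` in `[0, 1]`, with the
#'   seed and iteration count as attributes.
#' @export
fruchterman_reingold <- function(net, iterations = 500, seed) {
  stopifnot(inherits(net, "pcor_network"))
  if (missing(seed)) abort("`seed` is required for a reproducible layout.")
  p <- length(net$labels)
  if (p == 1) {
    coords <- matrix(0.5, 1, 2)
  } else {
    g <- igraph::graph_from_adjacency_matrix(
      abs(net$weights), mode = "undirected", weighted = TRUE, diag = FALSE
    )
    coords <- with_local_seed(seed, {
      igraph::layout_with_fr(g, niter = iterations,
                             weights = igraph::E(g)$weight)
    })
    rng <- apply(coords, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    coords <- sweep(sweep(coords, 2, rng[1, ]), 2, span, "/")
  }
  out <- tibble::tibble(node = net$labels, x = coords[, 1], y = coords[, 2])
  attr(out, "iterations") <- iterations
  attr(out, "seed") <- seed
  class(out) <- c("network_layout", class(out))
  out
}

#' Export a network and its bridge table to disk
#'
#' Writes, at full numeric precision: a node table (label, community, BEI,
#' coordinates), an edge table (with the cross-community flag), the complete
#' weight matrix, and a GraphML exchange file.
#'
#' @param net A `pcor_network`.
#' @param bridge_table Optional `bridge_table`; computed if missing.
#' @param layout Optional `network_layout`; omitted from the node table if
#'   missing.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
export_network <- function(net, bridge_table = NULL, layout = NULL, out_dir) {
  stopifnot(inherits(net, "pcor_network"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory: %s", out_dir))
  }
  if (is.null(bridge_table)) bridge_table <- bridge_expected_influence(net)
  nodes <- bridge_table
  if (!is.null(layout)) {
    nodes <- dplyr::left_join(nodes, layout, by = "node")
  }
  edges <- tidy(net, all_pairs = FALSE)
  wm <- tibble::as_tibble(net$weights, rownames = "node")
  paths <- c(
    nodes = file.path(out_dir, "node_table.csv"),
    edges = file.path(out_dir, "edge_table.csv"),
    weights = file.path(out_dir, "weight_matrix.csv"),
    graph = file.path(out_dir, "network.graphml")
  )
  readr::write_csv(nodes, paths["nodes"])
  readr::write_csv(edges, paths["edges"])
  readr::write_csv(wm, paths["weights"])
  g <- igraph::graph_from_adjacency_matrix(
    net$weights, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  igraph::V(g)$community <- unname(net$communities[net$labels])
  igraph::write_graph(g, paths["graph"], format = "graphml")
  invisible(paths)
}

derive_stage_seeds <- function(master_seed) {
  with_local_seed(master_seed, {
    setNames(sample.int(.Machine$integer.max, 3),
             c("edge_bootstrap", "case_drop", "layout"))
  })
}

#' Run the full symptom-network analysis pipeline
#'
#' Scoring, network estimation, bridge centrality, robustness bootstraps,
#' layout and export, in order, from a single configuration. Every stochastic
#' stage is seeded deterministically from one master seed, so the same
#' configuration always yields the identical report.
#'
#' @param config A named list, or path to a JSON file holding one, with
#'   fields (all optional unless noted): `input` (path to an item-level CSV
#'   or a data frame) or `scores` (a ready `node_scores` table; one of the
#'   two is required), `gamma` (0.5), `method` ("pearson"), `seed`
#'   (required), `B` (1000), `bootstrap` (TRUE), `grid` (0.05-0.75 by 0.05),
#'   `percentile` (80), `layout` (TRUE), `iterations` (500), `out_dir`
#'   (optional; report and tables are written there).
#' @return An `analysis_report` object (a structured list); if `out_dir` is
#'   set, also written as `report.json` plus the exported tables.
#' @export
#' @examples
#' spec <- make_true_network()
#' scores <- simulate_cohort(spec, n = 300, seed = 3)
#' rep <- run_pipeline(list(scores = scores, seed = 1, bootstrap = FALSE))
#' rep$bridge_nodes
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(gamma = 0.5, method = "pearson", B = 1000, bootstrap = TRUE,
         grid = seq(0.05, 0.75, by = 0.05), percentile = 80,
         layout = TRUE, iterations = 500, out_dir = NULL),
    config
  )
  if (is.null(cfg$seed)) abort("config must set `seed`.")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  warnings_log <- character(0)
  withCallingHandlers({
    retention <- NULL
    if (!is.null(cfg$scores)) {
      scores <- cfg$scores
      stopifnot(inherits(scores, "node_scores"))
    } else if (!is.null(cfg$input)) {
      resp <- stage("scoring", load_item_responses(cfg$input))
      retention <- glance(resp)
      scores <- stage("scoring", score_scales(resp))
    } else {
      abort("config must provide `scores` or `input`.")
    }
    seeds <- derive_stage_seeds(cfg$seed)
    net <- stage("estimate_network",
                 estimate_network(scores, gamma = cfg$gamma,
                                  method = cfg$method))
    bei <- stage("bridge", bridge_expected_influence(net))
    cross <- stage("bridge", cross_community_edges(net))
    bridges <- stage("bridge", select_bridge_nodes(bei, cfg$percentile))
    boot_summary <- NULL
    cs <- NULL
    if (isTRUE(cfg$bootstrap)) {
      boot <- stage("robustness",
                    bootstrap_edge_ci(scores, B = cfg$B, gamma = cfg$gamma,
                                      seed = seeds[["edge_bootstrap"]],
                                      method = cfg$method))
      cd <- stage("robustness",
                  case_drop_bootstrap(scores, grid = cfg$grid, B = cfg$B,
                                      seed = seeds[["case_drop"]],
                                      gamma = cfg$gamma, method = cfg$method))
      cs <- stage("robustness", cs_coefficient(cd))
      boot_summary <- list(
        edge_ci = tidy(boot),
        case_drop = tidy(cd),
        cs_coefficient = cs$value,
        cs_thresholds = c(cor = cs$cor_threshold, prob = cs$prob)
      )
    }
    lay <- NULL
    if (isTRUE(cfg$layout)) {
      lay <- stage("layout",
                   fruchterman_reingold(net, iterations = cfg$iterations,
                                        seed = seeds[["layout"]]))
    }
    report <- structure(
      list(
        config = cfg[setdiff(names(cfg), c("scores", "out_dir"))],
        stage_seeds = seeds,
        retention = retention,
        correlation_method = net$method,
        selected_lambda = net$lambda,
        network = glance(net),
        edges = tidy(net),
        cross_community = list(edges = tibble::as_tibble(cross),
                               summary = glance(cross)),
        bei = tibble::as_tibble(bei),
        bridge_nodes = bridges,
        bootstrap = boot_summary,
        layout = lay,
        warnings = warnings_log
      ),
      class = "analysis_report"
    )
    if (!is.null(cfg$out_dir)) {
      export_network(net, bei, lay, cfg$out_dir)
      jsonlite::write_json(
        report_to_json(report),
        file.path(cfg$out_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
      )
    }
    report
  }, warning = function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
}

report_to_json <- function(report) {
  x <- unclass(report)
  x$layout <- if (is.null(x$layout)) NULL else as.data.frame(x$layout)
  x$stage_seeds <- as.list(x$stage_seeds)
  x
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat(sprintf("  nodes: %d (%d communities), edges: %d, lambda = %.4g\n",
              x$network$n_nodes,
              length(unique(x$bei$community)),
              x$network$n_edges, x$selected_lambda))
  cat(sprintf("  cross-community edges: %d (positive share %s)\n",
              x$cross_community$summary$total,
              ifelse(is.na(x$cross_community$summary$positive_share), "n/a",
                     sprintf("%.2f%%", x$cross_community$summary$positive_share))))
  cat(sprintf("  bridge nodes (top %g%%): %s\n",
              x$config$percentile, paste(x$bridge_nodes, collapse = ", ")))
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  CS-coefficient (BEI): %.2f\n", x$bootstrap$cs_coefficient))
  }
  invisible(x)
}
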