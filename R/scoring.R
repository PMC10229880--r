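#' Load and validate item-level questionnaire responses
#'
#' Reads a rectangular table of Likert responses (rows = respondents,
#' columns = items), validates every cell against the admissible codes of its
#' scale, and drops incomplete or out-of-range rows (complete-case analysis:
#' incomplete questionnaires are treated as invalid, no imputation). The
#' retention rate (valid / submitted) is recorded on the returned object.
#'
#' @param data A data frame of responses, or a path to a delimited file with a
#'   header row naming the items. An optional `respondent_id` (or `id`) column
#'   is used as the respondent identifier; all other columns must be items
#'   covered by `defs`.
#' @param defs A list of [scale_definition()] objects covering all item
#'   columns (default [default_scale_definitions()]).
#'
#' @return An object of class `item_responses`: a list with `responses`
#'   (tibble of valid rows), `scale_of_item`, and the counts
#'   `n_submitted`, `n_valid`, `n_dropped` plus `retention` (percent).
#' @export
#' @examples
#' defs <- default_scale_definitions()
#' spec <- make_true_network()
#' items <- simulate_cohort(spec, n = 50, seed = 1, level = "item")
#' resp <- load_item_responses(items, defs)
#' glance(resp)
load_item_responses <- function(data, defs = default_scale_definitions()) {
  if (is.character(data)) {
    if (!file.exists(data)) abort(sprintf("file not found: %s", data))
    data <- readr::read_delim(data, show_col_types = FALSE, progress = FALSE)
  }
  data <- tibble::as_tibble(data)
  id_col <- intersect(c("respondent_id", "id"), names(data))[1]
  if (!is.na(id_col)) {
    ids <- as.character(data[[id_col]])
    data <- data[setdiff(names(data), id_col)]
  } else {
    ids <- as.character(seq_len(nrow(data)))
  }
  all_items <- unlist(lapply(defs, `[[`, "items"), use.names = FALSE)
  unknown <- setdiff(names(data), all_items)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown column(s) not covered by any scale definition: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  missing_items <- setdiff(all_items, names(data))
  if (length(missing_items) > 0) {
    abort(sprintf(
      "item column(s) missing from the data: %s",
      paste(missing_items, collapse = ", ")
    ))
  }
  scale_of_item <- unlist(lapply(defs, function(d) {
    setNames(rep(d$scale_name, length(d$items)), d$items)
  }))
  names(scale_of_item) <- unlist(lapply(defs, `[[`, "items"), use.names = FALSE)

  n_submitted <- nrow(data)
  valid <- rep(TRUE, n_submitted)
  for (d in defs) {
    for (item in d$items) {
      x <- data[[item]]
      ok <- !is.na(x) & x %in% d$level_codes
      valid <- valid & ok
    }
  }
  n_valid <- sum(valid)
  if (n_valid == 0) abort("no valid (complete, in-range) rows remain.")
  responses <- data[valid, all_items]
  responses <- dplyr::mutate(responses,
                             dplyr::across(dplyr::everything(), as.integer))
  responses <- dplyr::bind_cols(
    tibble::tibble(respondent_id = ids[valid]), responses
  )
  structure(
    list(
      responses = responses,
      scale_of_item = scale_of_item,
      defs = defs,
      n_submitted = n_submitted,
      n_valid = n_valid,
      n_dropped = n_submitted - n_valid,
      retention = 100 * n_valid / n_submitted
    ),
    class = "item_responses"
  )
}

#' @export
print.item_responses <- function(x, ...) {
  cat(sprintf(
    "<item_responses> %d valid of %d submitted (retention %.2f%%), %d items\n",
    x$n_valid, x$n_submitted, x$retention, ncol(x$responses) - 1
  ))
  invisible(x)
}

#' @export
glance.item_responses <- function(x, ...) {
  tibble::tibble(
    n_submitted = x$n_submitted,
    n_valid = x$n_valid,
    n_dropped = x$n_dropped,
    retention = x$retention
  )
}

#' Score scales into the node table of the symptom network
#'
#' Converts validated item responses into the respondent-by-node score table
#' the network is estimated on. Multi-item dimensions are scored as the sum
#' of their item codes; singleton dimensions keep the raw code. With the
#' default definitions this yields 14 nodes: A1-A5 (anxiety dimension sums)
#' and IGD1-IGD9 (raw item codes).
#'
#' @param responses An `item_responses` object from [load_item_responses()],
#'   or a plain data frame of already-validated item columns.
#' @param defs Scale definitions; defaults to those stored on `responses`,
#'   else [default_scale_definitions()].
#'
#' @return A `node_scores` tibble (`respondent_id` plus one column per node)
#'   carrying the node-to-community assignment as an attribute.
#' @export
#' @examples
#' spec <- make_true_network()
#' items <- simulate_cohort(spec, n = 50, seed = 1, level = "item")
#' scores <- score_scales(load_item_responses(items))
#' names(scores)
score_scales <- function(responses, defs = NULL) {
  if (inherits(responses, "item_responses")) {
    if (is.null(defs)) defs <- responses$defs
    data <- responses$responses
  } else {
    if (is.null(defs)) defs <- default_scale_definitions()
    data <- tibble::as_tibble(responses)
    if (!"respondent_id" %in% names(data)) {
      data <- dplyr::bind_cols(
        tibble::tibble(respondent_id = as.character(seq_len(nrow(data)))), data
      )
    }
  }
  cols <- list(respondent_id = data$respondent_id)
  for (d in defs) {
    if (any(lengths(d$dimensions) == 0)) {
      abort(sprintf("scale %s has a dimension with zero items.", d$scale_name))
    }
    for (i in seq_along(d$dimensions)) {
      label <- paste0(d$node_prefix, i)
      its <- d$dimensions[[i]]
      m <- as.matrix(data[its])
      cols[[label]] <- as.numeric(rowSums(m))
    }
  }
  out <- tibble::as_tibble(cols)
  new_node_scores(out, communities_of(defs))
}

new_node_scores <- function(tbl, communities) {
  stopifnot(setequal(setdiff(names(tbl), "respondent_id"), names(communities)))
  structure(
    tbl,
    communities = communities,
    class = c("node_scores", class(tibble::tibble()))
  )
}

#' Node-to-community assignment of a score table or network
#'
#' @param x A `node_scores` tibble or `pcor_network`.
#' @return Named character vector mapping node label to community.
#' @export
node_communities <- function(x) {
  if (inherits(x, "pcor_network")) return(x$communities)
  attr(x, "communities")
}

# numeric matrix of node scores (drops respondent_id), labels as colnames
score_matrix <- function(scores) {
  labels <- setdiff(names(scores), "respondent_id")
  m <- as.matrix(as.data.frame(scores)[labels])
  storage.mode(m) <- "double"
  m
}

#' Per-node descriptive statistics
#'
#' Mean and sample (n-1 denominator) standard deviation per node, the usual
#' reporting format for symptom-network studies.
#'
#' @param scores A `node_scores` tibble (or any data frame whose non-id
#'   columns are numeric node scores).
#' @return A tibble with columns `node`, `community`, `mean`, `sd`.
#' @export
descriptive_stats <- function(scores) {
  m <- score_matrix(scores)
  if (nrow(m) < 2) abort("need at least 2 respondents for descriptives.")
  comm <- node_communities(scores)
  tibble::tibble(
    node = colnames(m),
    community = if (is.null(comm)) NA_character_ else unname(comm[colnames(m)]),
    mean = unname(colMeans(m)),
    sd = unname(apply(m, 2, sd))
  )
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' \eqn{\alpha = k/(k-1) \cdot (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2}
#' are the item variances and \eqn{s_T^2} the variance of the total score,
#' all with the n-1 denominator.
#'
#' @param items A respondent-by-item numeric matrix or data frame
#'   (at least 2 items, 2 respondents).
#' @return The scalar reliability coefficient (at most 1).
#' @export
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 3, 5), c = c(2, 2, 4, 4))
#' cronbach_alpha(x)
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  storage.mode(m) <- "double"
  k <- ncol(m)
  if (k < 2) abort("need at least 2 items.")
  if (nrow(m) < 2) abort("need at least 2 respondents.")
  total_var <- var(rowSums(m))
  if (total_var == 0) abort("total-score variance is zero; alpha undefined.")
  item_var <- sum(apply(m, 2, var))
  k / (k - 1) * (1 - item_var / total_var)
}
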