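# Percentile-based sparsification of the true PPIN: drop edges by a
# link-prediction score threshold, then nodes by a centrality threshold,
# then clean up isolated nodes.

#' Linear-interpolation percentile
#'
#' The inclusive method: rank position `(q/100) * (n - 1)` on the sorted
#' values, linearly interpolated (base R quantile type 7).
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in (0, 100).
#' @return The percentile value.
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("empty value sequence", call. = FALSE)
  if (q <= 0 || q >= 100) stop("q must lie in (0, 100)", call. = FALSE)
  unname(stats::quantile(values, probs = q / 100, type = 7, names = FALSE))
}

#' Pruning thresholds for network refinement
#'
#' Defaults follow the discriminating attributes: edges whose Jaccard score
#' lies strictly above the 75th percentile are removed, and nodes whose
#' closeness centrality lies strictly below the 25th percentile are removed.
#' Cutoff values, when not supplied, are computed by [prune_network()] from
#' the un-pruned network's own attribute distributions (so re-applying the
#' same thresholds object is idempotent).
#'
#' @param edge_attribute Edge attribute to threshold (default `"jaccard"`).
#' @param edge_percentile Percentile for the edge rule (default 75).
#' @param node_attribute Node attribute to threshold (default `"closeness"`).
#' @param node_percentile Percentile for the node rule (default 25).
#' @param edge_rule Remove edges `"above"` (default) or `"below"` the edge
#'   cutoff; the `"below"` direction supports sensitivity analysis.
#' @param edge_cutoff_value,node_cutoff_value Optional precomputed cutoffs.
#' @return A list of class `pruning_thresholds`.
#' @export
pruning_thresholds <- function(edge_attribute = "jaccard", edge_percentile = 75,
                               node_attribute = "closeness", node_percentile = 25,
                               edge_rule = c("above", "below"),
                               edge_cutoff_value = NULL, node_cutoff_value = NULL) {
  stopifnot(edge_percentile > 0, edge_percentile < 100,
            node_percentile > 0, node_percentile < 100)
  structure(list(edge_attribute = edge_attribute,
                 edge_percentile = edge_percentile,
                 node_attribute = node_attribute,
                 node_percentile = node_percentile,
                 edge_rule = match.arg(edge_rule),
                 edge_cutoff_value = edge_cutoff_value,
                 node_cutoff_value = node_cutoff_value),
            class = "pruning_thresholds")
}

#' Prune a network by percentile thresholds on edge and node attributes
#'
#' Three steps, in order: (1) remove every edge whose `edge_attribute` value
#' is strictly above (or below, per `edge_rule`) the edge cutoff; (2) remove
#' every node whose `node_attribute` value is strictly below the node cutoff,
#' with its incident edges; (3) remove nodes left without any edge. Cutoffs
#' are the stated percentiles of the attribute distributions over the input
#' network's own edges and nodes, computed once before any removal.
#'
#' @param net Protein network to prune.
#' @param edge_scores Edge-score rows covering every edge of `net`.
#' @param node_rows Node-attribute rows covering every node of `net`.
#' @param thresholds A [pruning_thresholds()] object.
#' @return The pruned network; graph attribute `removal_report` holds the
#'   counts `edges_removed_by_score`, `nodes_removed_by_closeness`,
#'   `nodes_removed_isolated` and the computed cutoff values.
#' @export
prune_network <- function(net, edge_scores, node_rows,
                          thresholds = pruning_thresholds()) {
  validate_ppin(net)
  stopifnot(inherits(thresholds, "pruning_thresholds"))
  el <- igraph::as_edgelist(net)  # keep igraph's edge order for deletion below
  ekey <- if (nrow(el)) canonical_pairs(el[, 1], el[, 2])$key else character(0)
  cp <- canonical_pairs(edge_scores$protein_a, edge_scores$protein_b)
  missing_e <- setdiff(ekey, cp$key)
  if (length(missing_e) > 0L) {
    stop("edge_scores missing ", length(missing_e), " edge(s), e.g. ",
         gsub("\r", "-", utils::head(missing_e, 3))[1], call. = FALSE)
  }
  nodes <- igraph::V(net)$name
  missing_n <- setdiff(nodes, node_rows$node)
  if (length(missing_n) > 0L) {
    stop("node_rows missing ", length(missing_n), " node(s), e.g. ",
         missing_n[1], call. = FALSE)
  }
  eval_by_key <- setNames(edge_scores[[thresholds$edge_attribute]], cp$key)
  nval_by_node <- setNames(node_rows[[thresholds$node_attribute]], node_rows$node)
  evals <- unname(eval_by_key[ekey])
  nvals <- unname(nval_by_node[nodes])

  ecut <- thresholds$edge_cutoff_value %||% percentile(evals, thresholds$edge_percentile)
  ncut <- thresholds$node_cutoff_value %||% percentile(nvals, thresholds$node_percentile)

  drop_edge <- if (thresholds$edge_rule == "above") evals > ecut else evals < ecut
  g <- igraph::delete_edges(net, igraph::E(net)[drop_edge])
  drop_node <- nodes[nvals < ncut]
  g <- igraph::delete_vertices(g, drop_node)
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  g <- igraph::delete_vertices(g, isolated)

  report <- list(edges_removed_by_score = sum(drop_edge),
                 nodes_removed_by_closeness = length(drop_node),
                 nodes_removed_isolated = length(isolated),
                 edge_cutoff_value = ecut, node_cutoff_value = ncut,
                 nodes_remaining = igraph::vcount(g),
                 edges_remaining = igraph::ecount(g))
  g <- igraph::set_graph_attr(g, "removal_report", report)
  g
}
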