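# Link-prediction scores on node pairs. All four are computed on the given
# network's topology; for candidate (non-)edges the pair itself contributes
# nothing, matching standard link-prediction practice.

check_endpoints <- function(net, u, v) {
  missing <- setdiff(c(u, v), igraph::V(net)$name)
  if (length(missing) > 0L) {
    stop("node(s) not in network: ", paste(missing, collapse = ", "), call. = FALSE)
  }
}

# both endpoints are excluded from both neighborhoods; this only affects the
# jaccard union (an adjacent pair's mutual membership would otherwise dilute
# it), never the intersection
neighbor_sets <- function(net, u, v) {
  nu <- setdiff(names(igraph::neighbors(net, u)), c(u, v))
  nv <- setdiff(names(igraph::neighbors(net, v)), c(u, v))
  list(nu = nu, nv = nv)
}

#' Jaccard score of a node pair
#'
#' |N(u) n N(v)| / |N(u) u N(v)| over neighborhoods excluding the endpoints
#' u and v themselves; 0 when the union is empty. High values mean the pair
#' shares most of its neighbors -- in a PPIN, a strong sign of a genuine
#' interaction. For an edge of a triangle the score is 1: the two endpoints
#' share their single outside neighbor.
#'
#' @param net Protein network (igraph).
#' @param u,v Node identifiers.
#' @return Numeric in \[0, 1\].
#' @export
jaccard_score <- function(net, u, v) {
  check_endpoints(net, u, v)
  ns <- neighbor_sets(net, u, v)
  un <- union(ns$nu, ns$nv)
  if (length(un) == 0L) return(0)
  length(intersect(ns$nu, ns$nv)) / length(un)
}

#' Preferential-attachment score: deg(u) * deg(v)
#' @inheritParams jaccard_score
#' @return Non-negative integer.
#' @export
preferential_attachment <- function(net, u, v) {
  check_endpoints(net, u, v)
  unname(igraph::degree(net, u) * igraph::degree(net, v))
}

#' Common-neighbors score: |N(u) n N(v)|
#' @inheritParams jaccard_score
#' @return Non-negative integer.
#' @export
common_neighbors <- function(net, u, v) {
  check_endpoints(net, u, v)
  ns <- neighbor_sets(net, u, v)
  length(intersect(ns$nu, ns$nv))
}

#' Resource-allocation index: sum over shared neighbors z of 1/deg(z)
#'
#' Shared neighbors of low degree contribute more: they "allocate" their
#' connectivity over fewer partners. A shared neighbor always has degree >= 2
#' (it is adjacent to both endpoints), so the sum is well defined.
#'
#' @inheritParams jaccard_score
#' @return Non-negative numeric; 0 with no common neighbor.
#' @export
resource_allocation <- function(net, u, v) {
  check_endpoints(net, u, v)
  ns <- neighbor_sets(net, u, v)
  z <- intersect(ns$nu, ns$nv)
  if (length(z) == 0L) return(0)
  sum(1 / igraph::degree(net, z))
}

#' Score a set of node pairs with all four link-prediction metrics
#'
#' Computes jaccard, preferential attachment, common neighbors and resource
#' allocation for every pair, on the topology of `net`. Pairs from the false
#' network are scored on the *true* network's topology (pass the true network
#' as `net`), so that a candidate pair is judged by the observed
#' interactome around it.
#'
#' @param net Network supplying the topology.
#' @param pairs Data frame with columns `protein_a`, `protein_b` (and
#'   optionally `combined_score` for true edges).
#' @param origin Label, `"TRUE_EDGE"` or `"FALSE_EDGE"`.
#' @return Data frame with columns `protein_a`, `protein_b`, `origin`,
#'   `string_score` (NA for false edges), `jaccard`,
#'   `preferential_attachment`, `common_neighbors`, `resource_allocation`.
#' @export
score_edge_set <- function(net, pairs, origin = c("TRUE_EDGE", "FALSE_EDGE")) {
  origin <- match.arg(origin)
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  if (n == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      origin = character(), string_score = integer(),
                      jaccard = numeric(), preferential_attachment = numeric(),
                      common_neighbors = numeric(), resource_allocation = numeric()))
  }
  check_endpoints(net, pairs$protein_a, pairs$protein_b)
  # one adjacency-list pass; per-pair set arithmetic on integer indices
  idx <- setNames(seq_len(igraph::vcount(net)), igraph::V(net)$name)
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, as.integer)
  deg <- igraph::degree(net)
  ia <- idx[pairs$protein_a]; ib <- idx[pairs$protein_b]
  jac <- pa <- cn <- ra <- numeric(n)
  for (i in seq_len(n)) {
    ends <- c(ia[i], ib[i])
    nu <- setdiff(adj[[ia[i]]], ends); nv <- setdiff(adj[[ib[i]]], ends)
    z <- intersect(nu, nv)
    un <- length(nu) + length(nv) - length(z)
    jac[i] <- if (un == 0L) 0 else length(z) / un
    pa[i] <- deg[ia[i]] * deg[ib[i]]
    cn[i] <- length(z)
    ra[i] <- if (length(z) == 0L) 0 else sum(1 / deg[z])
  }
  data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
             origin = origin,
             string_score = if (origin == "TRUE_EDGE" && !is.null(pairs$combined_score))
               as.integer(pairs$combined_score) else NA_integer_,
             jaccard = jac, preferential_attachment = pa,
             common_neighbors = cn, resource_allocation = ra,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Edge data frame of a network (canonical order), with scores if present
#' @param net Protein network.
#' @return Data frame with `protein_a`, `protein_b` and, when the network
#'   carries a `combined_score` edge attribute, `combined_score`.
#' @export
edge_pairs <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character()))
  }
  cp <- canonical_pairs(el[, 1], el[, 2])
  df <- data.frame(protein_a = cp$u, protein_b = cp$v, stringsAsFactors = FALSE)
  sc <- igraph::edge_attr(net, "combined_score")
  if (!is.null(sc)) df$combined_score <- as.integer(sc)
  df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}
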