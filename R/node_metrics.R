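# Node topological attributes. Conventions (the networks here are routinely
# disconnected, so these matter):
#   * closeness: component-scaled Wasserman-Faust normalization,
#     ((n_c-1)/(N-1)) * ((n_c-1)/sum of within-component distances)
#   * betweenness: Brandes shortest-path betweenness / ((N-1)(N-2)/2),
#     endpoints excluded; 0 for graphs with N < 3
#   * eccentricity: per connected component; isolated node -> 0
#   * eigenvector: power iteration on the full adjacency matrix, unit
#     Euclidean norm; degenerate cross-component ties resolved toward the
#     largest component with a warning

#' Degree of every node
#' @param net Protein network (igraph).
#' @return Named integer vector.
#' @export
degree_all <- function(net) {
  igraph::degree(net)
}

#' Component-scaled normalized closeness centrality
#'
#' For node u in a component of size `n_c` within a graph of `N` nodes:
#' `((n_c - 1) / (N - 1)) * ((n_c - 1) / sum_v d(u, v))` with the sum over
#' u's own component (Wasserman-Faust scaling). Isolated nodes get 0. The
#' scaling makes values comparable across components and lie in \[0, 1\].
#'
#' @param net Protein network.
#' @return Named numeric vector.
#' @export
closeness_all <- function(net) {
  n <- igraph::vcount(net)
  out <- setNames(numeric(n), igraph::V(net)$name)
  if (n <= 1L) return(out)
  comp <- igraph::components(net)
  d <- igraph::distances(net)
  csize <- comp$csize[comp$membership]
  for (i in seq_len(n)) {
    nc <- csize[i]
    if (nc < 2L) next
    dsum <- sum(d[i, comp$membership == comp$membership[i]])
    out[i] <- ((nc - 1) / (n - 1)) * ((nc - 1) / dsum)
  }
  out
}

#' Eigenvector centrality by power iteration
#'
#' Entries of the principal eigenvector of the adjacency matrix, non-negative
#' and scaled to unit Euclidean norm. Computed by power iteration from a
#' uniform start vector; convergence when successive normalized iterates
#' differ by less than `tol` in max-norm. Iteration runs on `A + I` (a unit
#' diagonal shift): this leaves eigenvectors unchanged but breaks the +/-
#' lambda degeneracy of bipartite components that would otherwise make plain
#' power iteration oscillate. On disconnected graphs the dominant eigenvalue
#' may be (near-)degenerate across components; the tie is broken by
#' supporting the vector on the largest such component, with a warning.
#'
#' @param net Protein network with at least one edge.
#' @param tol Convergence tolerance (max-norm), default 1e-8.
#' @param max_iter Iteration budget, default 1000.
#' @return Named numeric vector with unit Euclidean norm.
#' @export
eigenvector_all <- function(net, tol = 1e-8, max_iter = 1000L) {
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0L) stop("eigenvector centrality needs >= 1 edge", call. = FALSE)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  comp <- igraph::components(net)
  # dominant eigenvalue per component, each by its own power iteration
  lambda <- numeric(comp$no)
  vecs <- vector("list", comp$no)
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) == 1L) { lambda[k] <- 0; vecs[[k]] <- 1; next }
    Ak <- A[members, members, drop = FALSE] + Matrix::Diagonal(length(members))
    x <- rep(1 / sqrt(length(members)), length(members))
    converged <- FALSE
    ny <- 0
    for (it in seq_len(max_iter)) {
      y <- as.numeric(Ak %*% x)
      ny <- sqrt(sum(y^2))
      y <- y / ny
      if (max(abs(y - x)) < tol) { x <- y; converged <- TRUE; break }
      x <- y
    }
    if (!converged) {
      stop(sprintf("power iteration did not converge within %d iterations", max_iter),
           call. = FALSE)
    }
    lambda[k] <- ny - 1  # undo the diagonal shift
    vecs[[k]] <- abs(x)
  }
  top <- max(lambda)
  winners <- which(lambda > top - max(tol, 1e-10))
  if (length(winners) > 1L) {
    warning("dominant eigenvalue is degenerate across components; ",
            "assigning centrality to the largest such component", call. = FALSE)
  }
  win <- winners[which.max(comp$csize[winners])]
  out <- setNames(numeric(n), igraph::V(net)$name)
  out[comp$membership == win] <- vecs[[win]]
  nrm <- sqrt(sum(out^2))
  if (nrm > 0) out <- out / nrm
  out
}

#' Normalized shortest-path betweenness centrality
#'
#' Brandes-style betweenness (endpoints excluded) divided by
#' `(N-1)(N-2)/2`, the number of node pairs a vertex could lie between in an
#' undirected graph. Nodes in graphs with fewer than 3 nodes get 0.
#'
#' @param net Protein network.
#' @return Named numeric vector in \[0, 1\].
#' @export
betweenness_all <- function(net) {
  n <- igraph::vcount(net)
  out <- setNames(numeric(n), igraph::V(net)$name)
  if (n < 3L) return(out)
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  out[] <- b / ((n - 1) * (n - 2) / 2)
  out
}

#' Local clustering coefficient
#'
#' For deg(u) >= 2: twice the number of edges among u's neighbors divided by
#' deg(u)(deg(u)-1); 0 otherwise.
#'
#' @param net Protein network.
#' @return Named numeric vector in \[0, 1\].
#' @export
clustering_coefficient_all <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) return(setNames(numeric(0), character(0)))
  cc <- igraph::transitivity(net, type = "localundirected",
                             vids = igraph::V(net), isolates = "zero")
  setNames(cc, igraph::V(net)$name)
}

#' Eccentricity within each node's connected component
#'
#' Maximum shortest-path distance from a node to any node of its own
#' component; isolated nodes get 0.
#'
#' @param net Protein network.
#' @return Named integer vector.
#' @export
eccentricity_all <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) return(setNames(integer(0), character(0)))
  e <- igraph::eccentricity(net, mode = "all")
  setNames(as.integer(e), igraph::V(net)$name)
}

#' Full node-attribute table
#'
#' One row per node with all six topological attributes, labeled with the
#' network of origin. An edgeless graph gets eigenvector centrality 0 for
#' every node (no principal direction exists).
#'
#' @param net Protein network.
#' @param origin Label, `"TRUE_NET"` or `"FALSE_NET"`.
#' @return Data frame with columns `node`, `origin`, `degree`, `closeness`,
#'   `eigenvector`, `betweenness`, `clustering_coefficient`, `eccentricity`.
#' @export
node_attribute_table <- function(net, origin = c("TRUE_NET", "FALSE_NET")) {
  origin <- match.arg(origin)
  n <- igraph::vcount(net)
  if (n == 0L) {
    return(data.frame(node = character(), origin = character(),
                      degree = integer(), closeness = numeric(),
                      eigenvector = numeric(), betweenness = numeric(),
                      clustering_coefficient = numeric(), eccentricity = integer()))
  }
  ev <- if (igraph::ecount(net) == 0L) {
    setNames(numeric(n), igraph::V(net)$name)
  } else {
    eigenvector_all(net)
  }
  data.frame(node = igraph::V(net)$name, origin = origin,
             degree = as.integer(degree_all(net)),
             closeness = unname(closeness_all(net)),
             eigenvector = unname(ev),
             betweenness = unname(betweenness_all(net)),
             clustering_coefficient = unname(clustering_coefficient_all(net)),
             eccentricity = unname(eccentricity_all(net)),
             stringsAsFactors = FALSE, row.names = NULL)
}
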