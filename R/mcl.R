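# Markov Cluster algorithm, written from scratch on sparse column-stochastic
# matrices. The flow process alternates expansion (matrix powering, which
# spreads probability mass along paths) and inflation (entry-wise powering
# plus column renormalization, which sharpens intra-cluster mass) until the
# matrix is (numerically) idempotent; clusters are read off the attractor
# structure of the limit.

#' MCL parameters
#'
#' @param expansion Integer matrix power per iteration (default 2).
#' @param inflation Entry-wise power (default 2.0); larger values give finer
#'   clusterings, values near 1 coarser ones.
#' @param self_loop_weight Weight added to the diagonal before normalization
#'   (default 1); self-loops damp the parity oscillations of bipartite-ish
#'   graphs and are canonical MCL practice.
#' @param prune_below Entries below this value are zeroed after inflation
#'   (default 1e-5), keeping the matrix sparse.
#' @param max_iterations Iteration budget (default 100).
#' @param convergence_tol Max-norm change declaring convergence (default 1e-8).
#' @return A list of class `mcl_params`.
#' @export
mcl_params <- function(expansion = 2L, inflation = 2.0, self_loop_weight = 1.0,
                       prune_below = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-8) {
  stopifnot(expansion >= 2L, inflation > 1, prune_below >= 0,
            max_iterations >= 1L, convergence_tol > 0)
  structure(list(expansion = as.integer(expansion), inflation = inflation,
                 self_loop_weight = self_loop_weight, prune_below = prune_below,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

#' Column-stochastic transition matrix of a network
#'
#' Adjacency matrix (1 per edge) plus `self_loop_weight` on the diagonal,
#' each column divided by its sum. An isolated node's column is a unit vector
#' on the diagonal.
#'
#' @param net Non-empty protein network.
#' @param self_loop_weight Diagonal weight (default 1).
#' @return A sparse column-stochastic `Matrix` with dimnames the node names.
#' @export
build_transition_matrix <- function(net, self_loop_weight = 1.0) {
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network", call. = FALSE)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE) * 1.0
  A <- A + Matrix::Diagonal(n, self_loop_weight)
  dimnames(A) <- list(igraph::V(net)$name, igraph::V(net)$name)
  normalize_columns(A)
}

normalize_columns <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  out <- M %*% Matrix::Diagonal(ncol(M), 1 / cs)
  dimnames(out) <- dimnames(M)  # Matrix products drop dimnames
  out
}

inflate <- function(M, inflation, prune_below) {
  M <- methods::as(M, "CsparseMatrix")
  M@x <- M@x^inflation
  M <- Matrix::drop0(M)
  if (prune_below > 0 && length(M@x)) {
    # never prune a column empty: keep each column's maximum entry
    colmax <- rep(0, ncol(M))
    cols <- rep(seq_len(ncol(M)), diff(M@p))
    for (j in seq_along(M@x)) {
      if (M@x[j] > colmax[cols[j]]) colmax[cols[j]] <- M@x[j]
    }
    keepable <- M@x >= prune_below | M@x >= colmax[cols]
    M@x[!keepable] <- 0
    M <- Matrix::drop0(M)
  }
  normalize_columns(M)
}

#' Run the MCL expansion/inflation iteration to convergence
#'
#' Repeats \[matrix power `expansion`; entry-wise power `inflation`; prune
#' entries below `prune_below`; renormalize columns\] until the max-norm
#' change between successive iterates falls below `convergence_tol` or the
#' iteration budget is exhausted (warning; result flagged non-converged).
#'
#' @param M Column-stochastic matrix from [build_transition_matrix()].
#' @param params [mcl_params()].
#' @return The converged matrix with attributes `converged` (logical) and
#'   `iterations` (integer).
#' @export
mcl_iterate <- function(M, params = mcl_params()) {
  check_column_stochastic(M)
  dn <- dimnames(M)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(params$max_iterations)) {
    E <- M
    for (k in seq_len(params$expansion - 1L)) E <- E %*% M
    Mnew <- inflate(E, params$inflation, params$prune_below)
    dimnames(Mnew) <- dn
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge within ", params$max_iterations,
            " iterations; returning the last iterate", call. = FALSE)
  }
  attr(M, "converged") <- converged
  attr(M, "iterations") <- it
  M
}

check_column_stochastic <- function(M, tol = 1e-9) {
  if (nrow(M) != ncol(M)) stop("matrix must be square", call. = FALSE)
  if (any(M < 0)) stop("matrix has negative entries", call. = FALSE)
  if (any(abs(Matrix::colSums(M) - 1) > tol)) {
    stop("matrix is not column-stochastic", call. = FALSE)
  }
  invisible(M)
}

#' Extract a hard partition from a converged MCL matrix
#'
#' Attractors are the rows with positive diagonal mass. Each node (column) is
#' assigned to the attractor row carrying its column's maximum mass (ties to
#' the smallest row index); attractor rows whose supports overlap are merged
#' by connected components, so the result is a hard partition.
#'
#' @param M Converged (or non-converged but flagged) MCL matrix with dimnames.
#' @return A `ppin_partition`: list with `membership` (named integer vector)
#'   and `clusters` (list of member name vectors), cluster ids ordered by
#'   descending size then lexicographically smallest member.
#' @export
extract_clusters <- function(M) {
  n <- ncol(M)
  nodes <- colnames(M) %||% as.character(seq_len(n))
  Md <- as.matrix(M)
  attractors <- which(diag(Md) > 0)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # non-converged fallback
  sub <- Md[attractors, , drop = FALSE]
  assign_attr <- attractors[apply(sub, 2, which.max)]  # ties -> smallest index
  # merge attractor rows with overlapping support (columns where both positive)
  k <- length(attractors)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  supp <- lapply(seq_len(k), function(i) which(sub[i, ] > 0))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j > i && length(intersect(supp[[i]], supp[[j]])) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  group_of_attr <- vapply(seq_len(k), find, integer(1))
  raw <- group_of_attr[match(assign_attr, attractors)]
  as_partition(setNames(raw, nodes))
}

# normalize raw cluster labels into the canonical partition object
as_partition <- function(raw_membership) {
  nodes <- names(raw_membership)
  blocks <- split(nodes, raw_membership)
  sizes <- lengths(blocks)
  minmember <- vapply(blocks, min, character(1))
  ord <- order(-sizes, minmember)
  blocks <- lapply(blocks[ord], sort)
  membership <- integer(length(nodes))
  names(membership) <- nodes
  for (i in seq_along(blocks)) membership[blocks[[i]]] <- i
  stopifnot(sum(lengths(blocks)) == length(nodes),
            !anyDuplicated(unlist(blocks)))  # hard-partition invariant
  structure(list(membership = membership, clusters = unname(blocks)),
            class = "ppin_partition")
}

#' @export
print.ppin_partition <- function(x, ...) {
  cat(sprintf("Partition of %d nodes into %d clusters (sizes: %s)\n",
              length(x$membership), length(x$clusters),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' Cluster a protein network with MCL
#'
#' Composes [build_transition_matrix()], [mcl_iterate()] and
#' [extract_clusters()].
#'
#' @param net Non-empty protein network.
#' @param params [mcl_params()].
#' @return A `ppin_partition` (see [extract_clusters()]).
#' @export
cluster_network <- function(net, params = mcl_params()) {
  M <- build_transition_matrix(net, params$self_loop_weight)
  Mc <- mcl_iterate(M, params)
  extract_clusters(Mc)
}

#' Cluster assignment table
#' @param partition A `ppin_partition`.
#' @param net Optional network supplying node roles.
#' @return Data frame with `node`, `cluster_id` and, when `net` is given,
#'   `role`.
#' @export
partition_table <- function(partition, net = NULL) {
  df <- data.frame(node = names(partition$membership),
                   cluster_id = unname(partition$membership),
                   stringsAsFactors = FALSE)
  if (!is.null(net)) {
    role <- setNames(igraph::V(net)$role, igraph::V(net)$name)
    df$role <- unname(role[df$node])
  }
  df[order(df$cluster_id, df$node), , drop = FALSE]
}
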