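# Brute-force oracles, independent of the package's code paths:
# set arithmetic on raw edge lists, explicit BFS / path enumeration, dense
# base-R linear algebra. They are deliberately naive.

# --- graph plumbing -------------------------------------------------------

# edges: data.frame(a, b) of character ids; nodes: character vector
o_adjlist <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges$a[i]; b <- edges$b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

o_neighbors <- function(edges, v) {
  unique(c(edges$b[edges$a == v], edges$a[edges$b == v]))
}

o_degree <- function(edges, v) length(o_neighbors(edges, v))

# random G(n, p) edge list over named nodes; optionally resampled until
# connected (checked by BFS reach)
rgraph_edges <- function(n, p, seed, connected = FALSE) {
  withr::with_seed(seed, {
    repeat {
      nodes <- sprintf("N%02d", seq_len(n))
      pairs <- t(combn(nodes, 2))
      keep <- runif(nrow(pairs)) < p
      edges <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                          stringsAsFactors = FALSE)
      if (!connected) break
      if (nrow(edges) > 0 &&
          sum(is.finite(o_bfs(o_adjlist(edges, nodes), nodes[1]))) == n) break
    }
    list(nodes = nodes, edges = edges)
  })
}

# build an igraph protein network directly (not via the package's builders)
make_net <- function(edges, nodes = NULL, targets = character(0)) {
  nodes <- nodes %||% unique(c(edges$a, edges$b))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes,
                          role = ifelse(nodes %in% targets, "TARGET", "INTERACTOR"),
                          stringsAsFactors = FALSE))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- shortest-path machinery ---------------------------------------------

# BFS distances from `from`; Inf for unreachable
o_bfs <- function(adj, from) {
  nodes <- names(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# BFS with shortest-path counts (sigma)
o_bfs_sigma <- function(adj, from) {
  nodes <- names(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  sigma <- setNames(rep(0, length(nodes)), nodes)
  dist[from] <- 0; sigma[from] <- 1
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  list(dist = dist, sigma = sigma)
}

# normalized betweenness via the pair-counting identity
# sigma_st(v) = sigma_s(v) * sigma_t(v) when d(s,v) + d(v,t) = d(s,t)
o_betweenness <- function(edges, nodes) {
  n <- length(nodes)
  out <- setNames(rep(0, n), nodes)
  if (n < 3) return(out)
  adj <- o_adjlist(edges, nodes)
  bfs <- lapply(setNames(nodes, nodes), function(s) o_bfs_sigma(adj, s))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- nodes[i]; t <- nodes[j]
    dst <- bfs[[s]]$dist[t]
    if (is.infinite(dst)) next
    for (v in nodes) {
      if (v == s || v == t) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst) {
        out[v] <- out[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
      }
    }
  }
  out / ((n - 1) * (n - 2) / 2)
}

# exhaustive simple-path enumeration betweenness (tiny graphs only)
o_betweenness_paths <- function(edges, nodes) {
  n <- length(nodes)
  out <- setNames(rep(0, n), nodes)
  if (n < 3) return(out)
  adj <- o_adjlist(edges, nodes)
  all_paths <- function(v, t, visited) {
    if (v == t) return(list(visited))
    res <- list()
    for (w in adj[[v]]) {
      if (!w %in% visited) res <- c(res, all_paths(w, t, c(visited, w)))
    }
    res
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(nodes[i], nodes[j], nodes[i])
    if (length(paths) == 0) next
    len <- vapply(paths, length, integer(1))
    shortest <- paths[len == min(len)]
    for (p in shortest) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) out[v] <- out[v] + 1 / length(shortest)
    }
  }
  out / ((n - 1) * (n - 2) / 2)
}

o_closeness <- function(edges, nodes) {
  n <- length(nodes)
  adj <- o_adjlist(edges, nodes)
  out <- setNames(rep(0, n), nodes)
  if (n <= 1) return(out)
  for (v in nodes) {
    d <- o_bfs(adj, v)
    reach <- d[is.finite(d)]
    nc <- length(reach)
    if (nc < 2) next
    out[v] <- ((nc - 1) / (n - 1)) * ((nc - 1) / sum(reach))
  }
  out
}

o_eccentricity <- function(edges, nodes) {
  adj <- o_adjlist(edges, nodes)
  vapply(setNames(nodes, nodes), function(v) {
    d <- o_bfs(adj, v)
    max(d[is.finite(d)])
  }, numeric(1))
}

o_clustering <- function(edges, nodes) {
  ekeys <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  vapply(setNames(nodes, nodes), function(v) {
    nb <- o_neighbors(edges, v)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (x in seq_len(k - 1)) for (y in (x + 1):k) {
      if (paste(pmin(nb[x], nb[y]), pmax(nb[x], nb[y])) %in% ekeys) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# principal eigenvector via dense eigendecomposition (connected graphs)
o_eigenvector <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$a[i], edges$b[i]] <- 1
    A[edges$b[i], edges$a[i]] <- 1
  }
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  setNames(v / sqrt(sum(v^2)), nodes)
}

# --- edge-score oracles ---------------------------------------------------

o_jaccard <- function(edges, u, v) {
  nu <- setdiff(o_neighbors(edges, u), c(u, v))
  nv <- setdiff(o_neighbors(edges, v), c(u, v))
  un <- union(nu, nv)
  if (length(un) == 0) 0 else length(intersect(nu, nv)) / length(un)
}
o_pa <- function(edges, u, v) o_degree(edges, u) * o_degree(edges, v)
o_cn <- function(edges, u, v) length(intersect(o_neighbors(edges, u), o_neighbors(edges, v)))
o_ra <- function(edges, u, v) {
  z <- intersect(o_neighbors(edges, u), o_neighbors(edges, v))
  if (length(z) == 0) return(0)
  sum(vapply(z, function(w) 1 / o_degree(edges, w), numeric(1)))
}

# --- statistics oracles ---------------------------------------------------

o_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

o_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1); vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

o_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

o_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  # step-up: running minimum from the largest rank down, capped at 1
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# --- naive dense MCL (base R; independent of the package's sparse path) ---

o_mcl_membership <- function(A, expansion = 2, inflation = 2, self_loop = 1,
                             prune = 1e-5, tol = 1e-8, max_iter = 100) {
  n <- nrow(A)
  M <- A + diag(self_loop, n)
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    E <- M
    for (k in seq_len(expansion - 1)) E <- E %*% M
    E <- E^inflation
    for (j in seq_len(n)) {
      cm <- max(E[, j])
      drop <- E[, j] < prune & E[, j] < cm
      E[drop, j] <- 0
    }
    E <- sweep(E, 2, colSums(E), "/")
    delta <- max(abs(E - M))
    M <- E
    if (delta < tol) break
  }
  attractors <- which(diag(M) > 0)
  assign_attr <- attractors[apply(M[attractors, , drop = FALSE], 2, which.max)]
  # merge attractors whose supports overlap
  lab <- setNames(seq_along(attractors), attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
      if (i >= j) next
      si <- which(M[attractors[i], ] > 0); sj <- which(M[attractors[j], ] > 0)
      if (length(intersect(si, sj)) > 0 && lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  membership <- lab[match(assign_attr, attractors)]
  setNames(as.integer(factor(membership)), rownames(A))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# --- exhaustive non-isomorphic connected graphs on 3..6 nodes -------------
# drawn from the published graph atlas (every non-isomorphic graph on up to
# 6 vertices is atlas index 0..208); 141 are connected with >= 3 nodes

connected_graph_atlas <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    reps <- list()
    for (idx in 0:208) {
      g <- igraph::graph_from_atlas(idx)
      n <- igraph::vcount(g)
      if (n < 3 || n > 6 || !igraph::is_connected(g)) next
      nodes <- sprintf("V%d", seq_len(n))
      el <- igraph::as_edgelist(g)
      reps[[length(reps) + 1]] <- list(
        nodes = nodes,
        edges = data.frame(a = nodes[el[, 1]], b = nodes[el[, 2]],
                           stringsAsFactors = FALSE))
    }
    cache <<- reps
    reps
  }
})
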