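#' Read a STRING-style scored protein links file
#'
#' Parses the STRING `protein.links` dialect: whitespace-separated columns
#' `protein1 protein2 combined_score`, where the combined score is an integer
#' confidence on the 0-1000 scale. An optional single header line (third token
#' not numeric) is skipped. Records listing the same unordered pair twice --
#' STRING files carry both orientations -- are collapsed to one record keeping
#' the maximum score.
#'
#' @param path Path to the links file.
#' @return A data frame of interaction records with columns `protein_a`,
#'   `protein_b`, `combined_score`, one row per unique unordered pair, in
#'   first-appearance order.
#' @export
read_string_links <- function(path) {
  if (!file.exists(path)) stop("links file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("links file is empty: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  start <- 1L
  if (length(toks[[1]]) >= 3L && is.na(suppressWarnings(as.numeric(toks[[1]][3])))) {
    start <- 2L  # header line
  }
  if (start > length(toks)) stop("links file has a header but no records: ", path, call. = FALSE)
  n <- length(toks) - start + 1L
  a <- character(n); b <- character(n); s <- integer(n)
  for (i in seq_len(n)) {
    line_no <- start + i - 1L
    f <- toks[[line_no]]
    if (length(f) < 3L) {
      stop(sprintf("malformed line %d: expected >= 3 fields, got %d", line_no, length(f)),
           call. = FALSE)
    }
    sc <- suppressWarnings(as.numeric(f[3]))
    if (is.na(sc) || sc != round(sc)) {
      stop(sprintf("malformed line %d: combined_score '%s' is not an integer", line_no, f[3]),
           call. = FALSE)
    }
    if (sc <= 0 || sc > 1000) {
      stop(sprintf("line %d: combined_score %d outside (0, 1000]", line_no, as.integer(sc)),
           call. = FALSE)
    }
    if (f[1] == f[2]) {
      stop(sprintf("line %d: self-interaction %s-%s rejected", line_no, f[1], f[2]),
           call. = FALSE)
    }
    a[i] <- f[1]; b[i] <- f[2]; s[i] <- as.integer(sc)
  }
  assert_protein_ids(c(a, b))
  cp <- canonical_pairs(a, b)
  # collapse duplicates (either orientation) keeping the maximum score
  best <- tapply(s, cp$key, max)
  first <- !duplicated(cp$key)
  data.frame(protein_a = cp$u[first], protein_b = cp$v[first],
             combined_score = as.integer(best[cp$key[first]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a target-protein list (one identifier per line)
#'
#' @param path Path to a plain-text file with one protein identifier per line.
#' @return Character vector of unique identifiers.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop("target list not found: ", path, call. = FALSE)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[nzchar(ids)]
  assert_protein_ids(ids, "target identifier")
  unique(ids)
}

#' Filter interaction records by minimum combined score
#'
#' Retains records whose combined score is at least `min_score`; a record
#' scoring exactly at the threshold is kept (only scores strictly below the
#' threshold are removed). The default threshold of 300 drops low-confidence
#' STRING interactions.
#'
#' @param records Interaction records from [read_string_links()].
#' @param min_score Minimum combined score to keep (default 300).
#' @return The retained records, input order preserved.
#' @export
filter_by_score <- function(records, min_score = 300) {
  stopifnot(is.data.frame(records), min_score >= 0)
  records[records$combined_score >= min_score, , drop = FALSE]
}

#' Build the true protein-protein interaction network
#'
#' Constructs an undirected simple graph whose nodes are every protein
#' appearing in the records and whose edges are the recorded interactions.
#' Each node carries a `role` attribute: `"TARGET"` if its identifier is in
#' `targets`, otherwise `"INTERACTOR"`. Targets with no recorded interaction
#' are excluded from the graph and reported via the graph attribute
#' `unmapped_targets`.
#'
#' @param records Interaction records (non-empty data frame).
#' @param targets Character vector of target-protein identifiers.
#' @return An igraph object with vertex attribute `role` and graph attributes
#'   `unmapped_targets` and `kind = "TRUE_NET"`.
#' @export
build_true_ppin <- function(records, targets = character()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no interaction records: cannot build a network", call. = FALSE)
  nodes <- unique(c(records$protein_a, records$protein_b))
  role <- ifelse(nodes %in% targets, "TARGET", "INTERACTOR")
  unmapped <- setdiff(targets, nodes)
  if (length(unmapped) > 0L) {
    message(length(unmapped), " target(s) absent from interaction records: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(
    records[, c("protein_a", "protein_b", "combined_score")],
    directed = FALSE,
    vertices = data.frame(name = nodes, role = role, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "unmapped_targets", unmapped)
  g <- igraph::set_graph_attr(g, "kind", "TRUE_NET")
  validate_ppin(g)
  g
}

#' Validate the protein-network invariants
#'
#' Checks that a graph is undirected and simple (no self-loops, no parallel
#' edges) and that every node has exactly one role in \{TARGET, INTERACTOR\}.
#'
#' @param net An igraph protein network.
#' @return The network, invisibly; errors if an invariant is violated.
#' @export
validate_ppin <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::is_directed(net)) stop("network must be undirected", call. = FALSE)
  if (any(igraph::which_loop(net))) stop("network contains self-loops", call. = FALSE)
  if (any(igraph::which_multiple(net))) stop("network contains parallel edges", call. = FALSE)
  role <- igraph::V(net)$role
  if (is.null(role) || any(is.na(role)) || !all(role %in% c("TARGET", "INTERACTOR"))) {
    stop("every node needs a role in {TARGET, INTERACTOR}", call. = FALSE)
  }
  invisible(net)
}

#' Node identifiers of the target proteins in a network
#' @param net An igraph protein network with a `role` vertex attribute.
#' @return Character vector of target node names.
#' @export
target_nodes <- function(net) {
  igraph::V(net)$name[igraph::V(net)$role == "TARGET"]
}

# enumerate all target-incident non-edges of net, canonical order, deduplicated
enumerate_false_pairs <- function(net) {
  tp <- target_nodes(net)
  all_nodes <- igraph::V(net)$name
  if (length(tp) == 0L) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  pieces <- lapply(tp, function(t) {
    nb <- names(igraph::neighbors(net, t))
    cand <- setdiff(all_nodes, c(t, nb))
    if (length(cand) == 0L) return(NULL)
    data.frame(a = t, b = cand, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df)) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  }
  cp <- canonical_pairs(df$a, df$b)
  keep <- !duplicated(cp$key)  # target-target non-edges appear twice
  out <- data.frame(protein_a = cp$u[keep], protein_b = cp$v[keep],
                    stringsAsFactors = FALSE)
  out[order(out$protein_a, out$protein_b), , drop = FALSE]
}

#' Build the false (non-interaction) network
#'
#' The contrast network has the same node set as the true network; its edges
#' are pairs with at least one TARGET endpoint that are *not* edges of the
#' true network. With `n_false_edges = "all"` every such non-edge is included;
#' otherwise `n_false_edges` pairs (default: as many as the true network has
#' edges, giving balanced classes for downstream two-sample comparisons) are
#' sampled uniformly without replacement under `seed`.
#'
#' @param true_net The true PPIN.
#' @param n_false_edges Number of false edges to sample, or `"all"`.
#' @param seed Integer seed for the sampler.
#' @return An igraph network on the same node set, graph attribute
#'   `kind = "FALSE_NET"`.
#' @export
build_false_ppin <- function(true_net, n_false_edges = igraph::ecount(true_net),
                             seed = 1L) {
  validate_ppin(true_net)
  if (igraph::vcount(true_net) < 2L) stop("need >= 2 nodes", call. = FALSE)
  pool <- enumerate_false_pairs(true_net)
  if (identical(n_false_edges, "all") || identical(n_false_edges, "ALL")) {
    chosen <- pool
  } else {
    n_false_edges <- as.integer(n_false_edges)
    if (n_false_edges > nrow(pool)) {
      stop(sprintf("requested %d false edges but only %d target-incident non-edges exist",
                   n_false_edges, nrow(pool)), call. = FALSE)
    }
    idx <- withr::with_seed(seed, sample.int(nrow(pool), n_false_edges))
    chosen <- pool[sort(idx), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    chosen, directed = FALSE,
    vertices = data.frame(name = igraph::V(true_net)$name,
                          role = igraph::V(true_net)$role,
                          stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "kind", "FALSE_NET")
  validate_ppin(g)
  g
}

#' Write a network as a role-annotated TSV edge list
#'
#' Columns: `protein_a`, `protein_b`, `role_a`, `role_b`; endpoints in
#' canonical (lexicographic) order within each row, rows sorted, UTF-8, LF
#' line endings. [read_edge_list()] reconstructs the same graph.
#'
#' @param net Protein network.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  validate_ppin(net)
  el <- igraph::as_edgelist(net)
  role <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  if (nrow(el) > 0L) {
    cp <- canonical_pairs(el[, 1], el[, 2])
    df <- data.frame(protein_a = cp$u, protein_b = cp$v,
                     role_a = unname(role[cp$u]), role_b = unname(role[cp$v]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$protein_a, df$protein_b), , drop = FALSE]
  } else {
    df <- data.frame(protein_a = character(), protein_b = character(),
                     role_a = character(), role_b = character())
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("protein_a\tprotein_b\trole_a\trole_b",
               if (nrow(df)) do.call(paste, c(df, sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a role-annotated TSV edge list written by [write_edge_list()]
#' @param path Input path.
#' @return An igraph protein network. A header-only file yields a node-free
#'   graph with a warning (isolated nodes are not represented in edge lists).
#' @export
read_edge_list <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) {
    warning("edge list is empty: returning a node-free graph", call. = FALSE)
    return(igraph::set_vertex_attr(igraph::make_empty_graph(0, directed = FALSE),
                                   "role", value = character(0)))
  }
  nodes <- data.frame(name = c(df$protein_a, df$protein_b),
                      role = c(df$role_a, df$role_b), stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(nodes$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(df[, c("protein_a", "protein_b")],
                                     directed = FALSE, vertices = nodes)
  validate_ppin(g)
  g
}
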