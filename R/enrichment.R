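# Pathway overrepresentation: one-sided hypergeometric test of each cluster
# against GMT gene sets, Benjamini-Hochberg FDR over the whole family, and
# cross-cluster overlapping-pathway reporting.

#' Read pathway gene sets from a GMT file
#'
#' GMT: one pathway per line, tab-separated fields `name`, `description`,
#' then one or more member genes. The universe defaults to the union of all
#' members; supply `universe` to override (e.g. all network proteins mappable
#' to genes).
#'
#' @param path Path to the GMT file.
#' @param universe Optional character vector overriding the default universe.
#' @return A list of class `gene_set_collection`: `pathways` (named list of
#'   member vectors), `descriptions` (named character), `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  pathways <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i),
           call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("GMT parse error at line %d: pathway '%s' has no members", i, f[1]),
           call. = FALSE)
    }
    pathways[[f[1]]] <- members
    descriptions[f[1]] <- f[2]
  }
  gene_set_collection(pathways, descriptions, universe)
}

#' Construct a gene-set collection
#' @param pathways Named list of member character vectors (no empty pathway).
#' @param descriptions Optional named character vector of pathway names.
#' @param universe Optional universe; defaults to the union of all members.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(pathways, descriptions = NULL, universe = NULL) {
  stopifnot(length(pathways) > 0L, !is.null(names(pathways)),
            all(lengths(pathways) > 0L))
  default_universe <- unique(unlist(pathways, use.names = FALSE))
  universe <- unique(universe %||% default_universe)
  outside <- setdiff(default_universe, universe)
  if (length(outside) > 0L) {
    stop("pathway member(s) outside the supplied universe, e.g. ", outside[1],
         call. = FALSE)
  }
  structure(list(pathways = pathways,
                 descriptions = descriptions %||% setNames(names(pathways), names(pathways)),
                 universe = universe),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$pathways), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$pathways[[id]]),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Upper-tail hypergeometric overrepresentation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at least
#' `k` pathway members when `n` cluster genes are drawn without replacement
#' from a universe of `N` genes of which `K` belong to the pathway.
#'
#' @param k Observed overlap count.
#' @param n Cluster genes in the universe.
#' @param K Pathway size.
#' @param N Universe size.
#' @return The one-sided p-value.
#' @export
hypergeom_overrep_p <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || n > N || K > N) {
    stop(sprintf("inconsistent counts: k=%d n=%d K=%d N=%d", k, n, K, N),
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Overrepresentation analysis of every cluster against every pathway
#'
#' For each (cluster, pathway) pair with overlap k >= 1, computes the
#' upper-tail hypergeometric p-value; q-values are BH-adjusted over the whole
#' family of tests; a pathway is significant in a cluster iff q <= alpha.
#' Cluster members absent from the universe are dropped (count logged).
#'
#' @param partition A `ppin_partition`.
#' @param gene_sets A `gene_set_collection`.
#' @param alpha FDR significance level (default 0.05).
#' @param id_map Optional named character vector (protein id -> gene symbol)
#'   applied to cluster members before testing.
#' @return A list of class `enrichment_result`: `table` (data frame with
#'   `cluster_id`, `pathway_id`, `pathway_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `q_value`, `significant`) and `overlap` (list with
#'   `by_pathway`, `shared_2plus`, `shared_3plus`).
#' @export
enrich_clusters <- function(partition, gene_sets, alpha = 0.05, id_map = NULL) {
  stopifnot(inherits(partition, "ppin_partition"),
            inherits(gene_sets, "gene_set_collection"),
            alpha > 0, alpha < 1)
  universe <- gene_sets$universe
  N <- length(universe)
  members <- lapply(partition$clusters, function(m) {
    if (!is.null(id_map)) {
      mapped <- id_map[m]
      m <- unname(mapped[!is.na(mapped)])
    }
    unique(m)
  })
  in_universe <- lapply(members, intersect, universe)
  orig <- sum(vapply(partition$clusters, function(m) length(unique(m)), integer(1)))
  dropped <- orig - sum(lengths(in_universe))
  if (dropped > 0L) {
    message(dropped, " cluster member(s) absent from the universe were dropped")
  }
  if (sum(lengths(in_universe)) == 0L) {
    stop("no cluster member maps into the gene-set universe", call. = FALSE)
  }
  rows <- list()
  for (ci in seq_along(in_universe)) {
    genes <- in_universe[[ci]]
    n <- length(genes)
    if (n == 0L) next
    for (pid in names(gene_sets$pathways)) {
      pw <- gene_sets$pathways[[pid]]
      k <- length(intersect(genes, pw))
      if (k < 1L) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = ci, pathway_id = pid,
        pathway_name = unname(gene_sets$descriptions[pid]),
        k = k, n = n, K = length(pw), N = N,
        p_value = hypergeom_overrep_p(k, n, length(pw), N),
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), pathway_id = character(),
               pathway_name = character(), k = integer(), n = integer(),
               K = integer(), N = integer(), p_value = numeric())
  tab$q_value <- if (nrow(tab)) bh_fdr(tab$p_value) else numeric(0)
  tab$significant <- tab$q_value <= alpha
  tab <- tab[order(tab$q_value, tab$p_value, tab$cluster_id, tab$pathway_id), ,
             drop = FALSE]
  rownames(tab) <- NULL
  sig <- tab[tab$significant, , drop = FALSE]
  by_pathway <- lapply(split(sig$cluster_id, sig$pathway_id), sort)
  structure(list(
    table = tab,
    overlap = list(
      by_pathway = by_pathway,
      shared_2plus = names(by_pathway)[lengths(by_pathway) >= 2L],
      shared_3plus = names(by_pathway)[lengths(by_pathway) >= 3L])),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d tests, %d significant; %d pathway(s) shared by >= 2 clusters, %d by >= 3\n",
              nrow(x$table), sum(x$table$significant),
              length(x$overlap$shared_2plus), length(x$overlap$shared_3plus)))
  invisible(x)
}
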