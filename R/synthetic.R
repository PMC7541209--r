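# Seeded synthetic inputs: a planted-community (stochastic block model)
# interaction network with STRING-style integer scores, a target list spread
# evenly over communities, and pathway gene sets with planted
# cluster-concentrated pathways. These stand in for the external target
# prediction / interaction database / pathway services so the whole pipeline
# runs at desk scale with known ground truth.

#' Specification of a synthetic scored interaction network
#'
#' Nodes are split into near-equal communities; within-community pairs get an
#' edge with probability `p_in`, between-community pairs with `p_out`.
#' Integer interaction scores are drawn uniformly from `score_range`
#' (STRING's observed 150-999 span) and within-community edges are shifted
#' upward by `score_bias` (clipped to the range), producing the weak
#' score-vs-topology correlation regime typical of real data.
#'
#' @param n_targets Number of target proteins, drawn evenly across
#'   communities (default 30).
#' @param n_interactors Number of non-target proteins (default 90).
#' @param n_communities Number of planted communities (default 6).
#' @param p_in Within-community edge probability (default 0.6).
#' @param p_out Between-community edge probability (default 0.02).
#' @param score_range Integer (low, high) score bounds (default c(150, 999)).
#' @param score_bias Upward shift of within-community scores (default 200).
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(n_targets = 30L, n_interactors = 90L,
                                   n_communities = 6L, p_in = 0.6, p_out = 0.02,
                                   score_range = c(150L, 999L), score_bias = 200,
                                   seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, n_communities >= 1L,
            score_range[1] < score_range[2], score_range[1] > 0,
            score_range[2] <= 1000, n_targets + n_interactors >= 2L)
  structure(list(n_targets = as.integer(n_targets),
                 n_interactors = as.integer(n_interactors),
                 n_communities = as.integer(n_communities),
                 p_in = p_in, p_out = p_out,
                 score_range = as.integer(score_range),
                 score_bias = score_bias, seed = as.integer(seed)),
            class = "synthetic_network_spec")
}

#' Generate a synthetic scored interaction network
#'
#' @param spec A [synthetic_network_spec()].
#' @return A list: `records` (data frame `protein_a`, `protein_b`,
#'   `combined_score`), `targets` (character vector), `community_labels`
#'   (named integer vector over all nodes). Fully reproducible from the
#'   spec's seed.
#' @export
generate_network <- function(spec = synthetic_network_spec()) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  n <- spec$n_targets + spec$n_interactors
  nodes <- sprintf("PROT%04d", seq_len(n))
  community <- setNames(rep_len(seq_len(spec$n_communities), n), nodes)
  n_pairs <- n * (n - 1) / 2
  same <- outer(community, community, "==")
  expected <- spec$p_in * sum(same[upper.tri(same)]) +
    spec$p_out * sum(!same[upper.tri(same)])
  if (expected < 1) stop("spec yields an (expectedly) edgeless graph", call. = FALSE)
  withr::with_seed(spec$seed, {
    iu <- which(upper.tri(same), arr.ind = TRUE)
    p <- ifelse(same[upper.tri(same)], spec$p_in, spec$p_out)
    keep <- stats::rbinom(n_pairs, 1, p) == 1
    a <- nodes[iu[keep, 1]]
    b <- nodes[iu[keep, 2]]
    within <- same[upper.tri(same)][keep]
    lo <- spec$score_range[1]; hi <- spec$score_range[2]
    score <- lo + floor(stats::runif(sum(keep)) * (hi - lo + 1))
    score <- pmin(hi, ifelse(within, score + round(spec$score_bias), score))
    # targets drawn evenly across communities
    per_comm <- split(nodes, community)
    quota <- rep(spec$n_targets %/% spec$n_communities, spec$n_communities) +
      (seq_len(spec$n_communities) <= spec$n_targets %% spec$n_communities)
    targets <- unlist(lapply(seq_len(spec$n_communities), function(k) {
      sample(per_comm[[k]], min(quota[k], length(per_comm[[k]])))
    }), use.names = FALSE)
  })
  cp <- canonical_pairs(a, b)
  ord <- order(cp$u, cp$v)
  list(records = data.frame(protein_a = cp$u[ord], protein_b = cp$v[ord],
                            combined_score = as.integer(score[ord]),
                            stringsAsFactors = FALSE),
       targets = sort(targets),
       community_labels = community)
}

#' Specification of synthetic pathway gene sets
#'
#' @param n_pathways Total pathways (default 40).
#' @param pathway_size_range Integer (min, max) members per pathway
#'   (default c(8, 20)).
#' @param n_planted Pathways concentrated in a home community (default 4).
#' @param planted_fraction Fraction of a planted pathway drawn from its home
#'   community (default 0.8).
#' @param shared_planted Also plant one pathway spread across 3 distinct
#'   communities (default TRUE) -- the ground truth for cross-cluster
#'   overlap detection.
#' @param seed Integer seed (default 1).
#' @return A list of class `synthetic_pathway_spec`.
#' @export
synthetic_pathway_spec <- function(n_pathways = 40L, pathway_size_range = c(8L, 20L),
                                   n_planted = 4L, planted_fraction = 0.8,
                                   shared_planted = TRUE, seed = 1L) {
  stopifnot(planted_fraction > 0, planted_fraction <= 1,
            n_planted <= n_pathways, pathway_size_range[1] >= 2L,
            pathway_size_range[1] <= pathway_size_range[2])
  structure(list(n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_planted = as.integer(n_planted),
                 planted_fraction = planted_fraction,
                 shared_planted = isTRUE(shared_planted),
                 seed = as.integer(seed)),
            class = "synthetic_pathway_spec")
}

#' Generate synthetic pathway gene sets with planted community concentration
#'
#' Background pathways are sampled uniformly from all nodes. Each planted
#' pathway draws `planted_fraction` of its members from its home community
#' and the rest from elsewhere. With `shared_planted`, one extra pathway
#' draws its members evenly from 3 distinct communities, so that after
#' clustering it should surface as significant in several clusters at once.
#'
#' @param community_labels Named integer vector (node -> community id).
#' @param spec A [synthetic_pathway_spec()].
#' @return A list: `collection` (a `gene_set_collection` whose universe is
#'   all nodes) and `manifest` (planted ground truth: data frame with
#'   `pathway_id`, `kind`, `home_communities`).
#' @export
generate_pathways <- function(community_labels, spec = synthetic_pathway_spec()) {
  stopifnot(inherits(spec, "synthetic_pathway_spec"), length(community_labels) > 0L)
  nodes <- names(community_labels)
  comms <- sort(unique(community_labels))
  if (spec$shared_planted && length(comms) < 3L) {
    stop("shared planted pathway needs >= 3 communities", call. = FALSE)
  }
  lo <- spec$pathway_size_range[1]; hi <- spec$pathway_size_range[2]
  if (hi > length(nodes)) stop("pathway size exceeds the universe", call. = FALSE)
  pathways <- list()
  manifest <- list()
  withr::with_seed(spec$seed, {
    n_background <- spec$n_pathways - spec$n_planted - spec$shared_planted
    if (n_background < 0L) stop("n_planted (+ shared) exceeds n_pathways", call. = FALSE)
    for (i in seq_len(n_background)) {
      size <- sample(lo:hi, 1)
      id <- sprintf("PW_BG_%02d", i)
      pathways[[id]] <- sort(sample(nodes, size))
      manifest[[id]] <- list(kind = "background", home = integer(0))
    }
    for (i in seq_len(spec$n_planted)) {
      home <- comms[((i - 1L) %% length(comms)) + 1L]
      members_home <- nodes[community_labels == home]
      size <- sample(lo:hi, 1)
      n_home <- min(length(members_home), max(1L, round(spec$planted_fraction * size)))
      rest <- sample(setdiff(nodes, members_home), size - n_home)
      id <- sprintf("PW_PLANTED_%02d", i)
      pathways[[id]] <- sort(c(sample(members_home, n_home), rest))
      manifest[[id]] <- list(kind = "planted", home = home)
    }
    if (spec$shared_planted) {
      # the cross-module pathway is coextensive with its three home
      # communities: an unambiguous ground truth, so that failing to recover
      # it indicts the pipeline rather than the fixture
      homes <- sample(comms, 3)
      mem <- nodes[community_labels %in% homes]
      pathways[["PW_SHARED"]] <- sort(unique(mem))
      manifest[["PW_SHARED"]] <- list(kind = "shared", home = sort(homes))
    }
  })
  man <- data.frame(
    pathway_id = names(manifest),
    kind = vapply(manifest, `[[`, character(1), "kind"),
    home_communities = vapply(manifest, function(m) paste(m$home, collapse = ","),
                              character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(collection = gene_set_collection(pathways, universe = nodes),
       manifest = man)
}

#' Paired node-attribute fixture with a controlled closeness separation
#'
#' Two node-attribute tables whose closeness column differs in mean by
#' `separation` standard deviations while every other column is exchangeable
#' between origins -- a calibrated fixture for classifier-ranking tests.
#'
#' @param n Rows per table (>= 10).
#' @param separation Mean shift of the closeness column, in SD units.
#' @param seed Integer seed.
#' @return A list with `true_rows` and `false_rows` node-attribute tables.
#' @export
generate_false_attribute_fixture <- function(n, separation, seed = 1L) {
  stopifnot(n >= 10L)
  make_tab <- function(prefix, shift, origin) {
    data.frame(node = sprintf("%s%04d", prefix, seq_len(n)), origin = origin,
               degree = stats::rnorm(n), closeness = stats::rnorm(n, mean = shift),
               eigenvector = stats::rnorm(n), betweenness = stats::rnorm(n),
               clustering_coefficient = stats::rnorm(n),
               eccentricity = stats::rnorm(n),
               stringsAsFactors = FALSE)
  }
  withr::with_seed(seed, {
    true_rows <- make_tab("T", separation, "TRUE_NET")
    false_rows <- make_tab("F", 0, "FALSE_NET")
  })
  list(true_rows = true_rows, false_rows = false_rows)
}
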