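# End-to-end orchestration: build -> attributes -> selection -> prune ->
# cluster -> enrich, with every intermediate artifact written to the run
# directory and a machine-readable run report.

#' Pipeline configuration
#'
#' Defaults follow the analysis conventions of the package: STRING combined
#' score threshold 300 (inclusive keep), balanced false-edge sampling,
#' 75th/25th percentile pruning on jaccard/closeness, MCL inflation 2.0,
#' enrichment FDR 0.05. One global seed feeds stage-derived seeds (see
#' [derive_seed()]).
#'
#' @param links_file STRING-style scored links file.
#' @param targets_file Target list, one identifier per line.
#' @param gmt_file Pathway gene sets (GMT).
#' @param out_dir Output directory for all artifacts.
#' @param id_map_file Optional two-column TSV (protein_id, gene_symbol).
#' @param universe_file Optional one-per-line universe list for enrichment.
#' @param min_score Minimum combined score (default 300).
#' @param false_edges `"balanced"` (default; as many as true edges), `"all"`,
#'   or an integer count.
#' @param edge_percentile,node_percentile Pruning percentiles (defaults 75, 25).
#' @param mcl [mcl_params()].
#' @param alpha Enrichment FDR level (default 0.05).
#' @param n_folds Cross-validation folds for the node classifier (default 5).
#' @param seed Global seed (default 1).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(links_file, targets_file, gmt_file, out_dir,
                            id_map_file = NULL, universe_file = NULL,
                            min_score = 300, false_edges = "balanced",
                            edge_percentile = 75, node_percentile = 25,
                            mcl = mcl_params(), alpha = 0.05, n_folds = 5L,
                            seed = 1L) {
  structure(list(links_file = links_file, targets_file = targets_file,
                 gmt_file = gmt_file, out_dir = out_dir,
                 id_map_file = id_map_file, universe_file = universe_file,
                 min_score = min_score, false_edges = false_edges,
                 edge_percentile = edge_percentile,
                 node_percentile = node_percentile, mcl = mcl, alpha = alpha,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; `mcl` may be a mapping
#' of [mcl_params()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  required <- c("links_file", "targets_file", "gmt_file", "out_dir")
  missing <- setdiff(required, names(y))
  if (length(missing) > 0L) {
    stop("config missing required key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$mcl)) y$mcl <- do.call(mcl_params, y$mcl)
  do.call(pipeline_config, y)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(colnames(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(lapply(df, format_tsv_col), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

format_tsv_col <- function(x) {
  if (is.double(x)) formatC(x, digits = 6, format = "g") else as.character(x)
}

log_stage <- function(lines, msg, verbose = TRUE) {
  if (verbose) message("[netpharm] ", msg)
  c(lines, msg)
}

#' Run the full network-pharmacology pipeline
#'
#' Executes, in order: read + score-filter the links file; build the true
#' PPIN and the sampled false PPIN; compute edge link-prediction scores and
#' node centralities for both networks; attribute selection (score
#' correlations, edge-attribute Welch tests, node-attribute classifier
#' ranking); percentile pruning of the true PPIN; MCL clustering of the
#' pruned network; pathway overrepresentation of the clusters with
#' cross-cluster overlap reporting. All artifacts are written under
#' `config$out_dir`; the run is deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress to stderr (default TRUE).
#' @return The run report (list), invisibly also written as `report.json`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- character()
  stage <- "read"
  report <- list(package_version = as.character(utils::packageVersion("netpharm")),
                 config = config[setdiff(names(config), "mcl")],
                 mcl_params = unclass(config$mcl),
                 timestamp = format(Sys.time(), tz = "UTC"))
  tryCatch({
    records <- read_string_links(config$links_file)
    targets <- read_target_list(config$targets_file)
    kept <- filter_by_score(records, config$min_score)
    log_lines <- log_stage(log_lines, sprintf(
      "read: %d records, %d kept at min_score=%d", nrow(records), nrow(kept),
      as.integer(config$min_score)), verbose)
    if (nrow(kept) == 0L) {
      stop("no interactions at or above min_score = ", config$min_score, call. = FALSE)
    }
    report$n_records <- nrow(records)
    report$n_records_kept <- nrow(kept)

    stage <- "build"
    true_net <- build_true_ppin(kept, targets)
    n_false <- switch(as.character(config$false_edges),
                      balanced = igraph::ecount(true_net),
                      all = "all",
                      as.integer(config$false_edges))
    false_net <- build_false_ppin(true_net, n_false,
                                  seed = derive_seed(config$seed, "false_ppin"))
    write_edge_list(true_net, out("edges.tsv"))
    write_edge_list(false_net, out("false_edges.tsv"))
    report$true_net <- list(nodes = igraph::vcount(true_net),
                            edges = igraph::ecount(true_net),
                            targets = length(target_nodes(true_net)),
                            unmapped_targets = length(
                              igraph::graph_attr(true_net, "unmapped_targets")))
    report$false_net <- list(nodes = igraph::vcount(false_net),
                             edges = igraph::ecount(false_net))
    log_lines <- log_stage(log_lines, sprintf(
      "build: true %d nodes / %d edges; false %d edges",
      igraph::vcount(true_net), igraph::ecount(true_net),
      igraph::ecount(false_net)), verbose)

    stage <- "attributes"
    true_scores <- score_edge_set(true_net, edge_pairs(true_net), "TRUE_EDGE")
    # false pairs are scored on the true network's topology
    false_scores <- score_edge_set(true_net, edge_pairs(false_net), "FALSE_EDGE")
    edge_scores <- rbind(true_scores, false_scores)
    write_tsv(edge_scores, out("edge_scores.tsv"))
    true_nodes_tab <- node_attribute_table(true_net, "TRUE_NET")
    false_nodes_tab <- node_attribute_table(false_net, "FALSE_NET")
    write_tsv(rbind(true_nodes_tab, false_nodes_tab), out("node_scores.tsv"))
    log_lines <- log_stage(log_lines, sprintf(
      "attributes: %d edge rows, %d node rows",
      nrow(edge_scores), nrow(true_nodes_tab) + nrow(false_nodes_tab)), verbose)

    stage <- "selection"
    corr <- correlate_edge_attributes(true_scores)
    edge_rank <- rank_edge_attributes(true_scores, false_scores)
    node_rank <- rank_node_attributes(true_nodes_tab, false_nodes_tab,
                                      n_folds = config$n_folds,
                                      seed = derive_seed(config$seed, "classifier"))
    write_tsv(edge_rank, out("selection.tsv"))
    write_tsv(node_rank$importance, out("node_importance.tsv"))
    report$score_correlations <- setNames(as.list(corr$r), corr$variable_y)
    report$top_edge_attribute <- attr(edge_rank, "top_attribute")
    report$top_node_attribute <- node_rank$top_attribute
    report$node_classifier_auc <- node_rank$cv_auc
    log_lines <- log_stage(log_lines, sprintf(
      "selection: edge winner %s, node winner %s (AUC %.3f)",
      report$top_edge_attribute, report$top_node_attribute,
      node_rank$cv_auc), verbose)

    stage <- "prune"
    thr <- pruning_thresholds(edge_percentile = config$edge_percentile,
                              node_percentile = config$node_percentile)
    pruned <- prune_network(true_net, true_scores, true_nodes_tab, thr)
    write_edge_list(pruned, out("pruned.tsv"))
    report$pruning <- igraph::graph_attr(pruned, "removal_report")
    log_lines <- log_stage(log_lines, sprintf(
      "prune: %d nodes / %d edges remain", igraph::vcount(pruned),
      igraph::ecount(pruned)), verbose)

    stage <- "cluster"
    partition <- cluster_network(pruned, config$mcl)
    write_tsv(partition_table(partition, pruned), out("clusters.tsv"))
    report$n_clusters <- length(partition$clusters)
    report$cluster_sizes <- lengths(partition$clusters)
    log_lines <- log_stage(log_lines, sprintf(
      "cluster: %d clusters", report$n_clusters), verbose)

    stage <- "enrich"
    universe <- if (!is.null(config$universe_file))
      read_target_list(config$universe_file) else NULL
    gene_sets <- read_gmt(config$gmt_file, universe = universe)
    id_map <- NULL
    if (!is.null(config$id_map_file)) {
      m <- read.table(config$id_map_file, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
      id_map <- setNames(m[[2]], m[[1]])
    }
    enr <- enrich_clusters(partition, gene_sets, alpha = config$alpha,
                           id_map = id_map)
    write_tsv(enr$table, out("enrichment.tsv"))
    overlap_df <- data.frame(
      pathway_id = names(enr$overlap$by_pathway),
      cluster_ids = vapply(enr$overlap$by_pathway, paste, character(1),
                           collapse = ","),
      n_clusters = lengths(enr$overlap$by_pathway),
      stringsAsFactors = FALSE, row.names = NULL)
    write_tsv(overlap_df, out("overlap.tsv"))
    report$n_enrichment_tests <- nrow(enr$table)
    report$n_significant <- sum(enr$table$significant)
    report$pathways_shared_2plus <- enr$overlap$shared_2plus
    report$pathways_shared_3plus <- enr$overlap$shared_3plus
    log_lines <- log_stage(log_lines, sprintf(
      "enrich: %d significant of %d tests; %d pathway(s) shared by >= 3 clusters",
      report$n_significant, report$n_enrichment_tests,
      length(enr$overlap$shared_3plus)), verbose)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, out("run.log"))
  invisible(report)
}

#' Write synthetic pipeline inputs to a directory
#'
#' Generates the synthetic network, target list and pathway GMT under the
#' study's default conditions and writes them in the same formats the real
#' pipeline reads (`links.txt`, `targets.txt`, `pathways.gmt`,
#' `manifest.json`, `communities.tsv`).
#'
#' @param dir Output directory.
#' @param net_spec A [synthetic_network_spec()].
#' @param pw_spec A [synthetic_pathway_spec()].
#' @return Named list of the written file paths, invisibly.
#' @export
write_synthetic_inputs <- function(dir, net_spec = synthetic_network_spec(),
                                   pw_spec = synthetic_pathway_spec()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(net_spec)
  pws <- generate_pathways(net$community_labels, pw_spec)
  paths <- list(links = file.path(dir, "links.txt"),
                targets = file.path(dir, "targets.txt"),
                gmt = file.path(dir, "pathways.gmt"),
                manifest = file.path(dir, "manifest.json"),
                communities = file.path(dir, "communities.tsv"))
  links <- net$records
  writeLines(c("protein1 protein2 combined_score",
               paste(links$protein_a, links$protein_b, links$combined_score)),
             paths$links)
  writeLines(net$targets, paths$targets)
  write_gmt(pws$collection, paths$gmt)
  jsonlite::write_json(pws$manifest, paths$manifest, auto_unbox = TRUE)
  write_tsv(data.frame(node = names(net$community_labels),
                       community = unname(net$community_labels)),
            paths$communities)
  invisible(paths)
}
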