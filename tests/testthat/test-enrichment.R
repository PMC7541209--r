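test_that("GMT parsing builds the collection and validates lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c("PW1\tfirst pathway\tG1\tG2\tG3",
               "PW2\tsecond pathway\tG3\tG4\tG5\tG6"), f)
  gs <- read_gmt(f)
  expect_length(gs$pathways, 2L)
  expect_length(gs$universe, 6L)  # union with one shared gene
  expect_equal(gs$descriptions[["PW2"]], "second pathway")

  writeLines(character(0), f)
  expect_error(read_gmt(f), "empty")
  writeLines(c("PW1\tok\tG1", "PW2\tonlytwo"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("gene-set collections round-trip through GMT", {
  nodes <- sprintf("G%03d", 1:200)
  pws <- withr::with_seed(81, {
    setNames(lapply(1:50, function(i) sort(sample(nodes, sample(5:20, 1)))),
             sprintf("PW%02d", 1:50))
  })
  gs <- gene_set_collection(pws)
  f <- tempfile(fileext = ".gmt")
  write_gmt(gs, f)
  back <- read_gmt(f)
  expect_equal(back$pathways, gs$pathways)
  expect_setequal(back$universe, gs$universe)
})

test_that("hypergeometric upper tail matches explicit combinatorics", {
  expect_equal(hypergeom_overrep_p(0, 5, 5, 10), 1.0)
  expect_equal(hypergeom_overrep_p(5, 5, 5, 10), 1 / 252)  # C(5,5)C(5,0)/C(10,5)
  expect_error(hypergeom_overrep_p(6, 5, 5, 10), "inconsistent")
  expect_error(hypergeom_overrep_p(2, 5, 5, 4), "inconsistent")

  withr::with_seed(82, {
    for (i in 1:50) {
      N <- sample(4:25, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
      k <- sample(0:min(n, K), 1)
      expect_equal(hypergeom_overrep_p(k, n, K, N), o_hyper_tail(k, n, K, N),
                   tolerance = 1e-12)
    }
  })
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 1.0)), c(0.04, 0.04, 0.04, 1.0))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  p <- withr::with_seed(83, runif(100))
  q <- bh_fdr(p)
  expect_equal(q, o_bh(p), tolerance = 1e-12)
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  expect_true(all(q >= p - 1e-12))               # never below the raw p
  expect_true(all(q <= 1))
})

make_partition <- function(blocks) {
  raw <- rep(seq_along(blocks), lengths(blocks))
  names(raw) <- unlist(blocks)
  netpharm:::as_partition(raw)
}

test_that("a cluster coinciding with a pathway is significant", {
  universe <- sprintf("G%03d", 1:100)
  pws <- withr::with_seed(84, c(
    list(PW_HIT = universe[1:10]),
    setNames(lapply(1:9, function(i) sample(universe, 10)), paste0("PW_BG", 1:9))))
  gs <- gene_set_collection(pws, universe = universe)
  part <- make_partition(list(universe[1:10], universe[11:100]))
  res <- enrich_clusters(part, gs, alpha = 0.05)
  small_cluster <- unname(part$membership[universe[1]])
  hit <- res$table[res$table$pathway_id == "PW_HIT" &
                     res$table$cluster_id == small_cluster, ]
  expect_true(hit$significant)
  expect_equal(hit$k, 10L)

  # invariance under cluster relabeling (same blocks, different order)
  part2 <- make_partition(list(universe[11:100], universe[1:10]))
  res2 <- enrich_clusters(part2, gs, alpha = 0.05)
  expect_equal(sort(res$table$p_value), sort(res2$table$p_value))
})

test_that("id mapping and universe filtering are applied", {
  universe <- sprintf("G%03d", 1:50)
  gs <- gene_set_collection(list(PW = universe[1:10]), universe = universe)
  prot <- sprintf("P%03d", 1:12)
  id_map <- setNames(universe[1:10], prot[1:10])  # two proteins unmapped
  part <- make_partition(list(prot))
  expect_message(res <- enrich_clusters(part, gs, id_map = id_map), "dropped")
  expect_equal(res$table$k, 10L)
  expect_equal(res$table$n, 10L)

  unmappable <- make_partition(list(c("X1", "X2")))
  expect_error(enrich_clusters(unmappable, gs), "universe")
})

test_that("a pathway planted across three communities lands in the 3+ overlap list", {
  net_data <- generate_network(synthetic_network_spec(seed = 1))
  pws <- generate_pathways(net_data$community_labels,
                           synthetic_pathway_spec(seed = 1))
  # clusters = true communities (the clustering stage is tested elsewhere)
  comm <- net_data$community_labels
  part <- make_partition(split(names(comm), comm))
  res <- enrich_clusters(part, pws$collection, alpha = 0.05)
  shared_id <- pws$manifest$pathway_id[pws$manifest$kind == "shared"]
  expect_true(shared_id %in% res$overlap$shared_3plus)
  homes <- as.integer(strsplit(pws$manifest$home_communities[
    pws$manifest$kind == "shared"], ",")[[1]])
  home_cluster_ids <- vapply(homes, function(h) {
    unname(part$membership[names(comm)[comm == h][1]])
  }, integer(1))
  expect_setequal(res$overlap$by_pathway[[shared_id]], home_cluster_ids)
})
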