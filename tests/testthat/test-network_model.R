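write_links <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("STRING links parsing collapses duplicates, skips headers, validates", {
  # both orientations collapse to one record keeping the max score
  rec <- read_string_links(write_links(c("P1 P2 400", "P2 P1 350")))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$combined_score, 400L)
  expect_equal(sort(c(rec$protein_a, rec$protein_b)), c("P1", "P2"))

  # header line with non-numeric third token is skipped
  rec <- read_string_links(write_links(c("protein1 protein2 combined_score",
                                         "A B 500", "A C 900")))
  expect_equal(nrow(rec), 2L)

  expect_error(read_string_links(write_links("P1 P1 500")), "self-interaction")
  expect_error(read_string_links(write_links(c("A B 300", "A C"))), "line 2")
  expect_error(read_string_links(write_links("A B 1500")), "outside")
  expect_error(read_string_links(write_links("A B 0")), "outside")
  expect_error(read_string_links(tempfile()), "not found")
})

test_that("parsed records round-trip through the edge-list writer", {
  lines <- c("A B 500", "B C 400", "C D 300", "D E 200", "A E 999")
  rec <- read_string_links(write_links(lines))
  expect_equal(nrow(rec), 5L)
  net <- build_true_ppin(rec, targets = "A")
  f <- tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  expect_equal(edge_pairs(back)[, c("protein_a", "protein_b")],
               edge_pairs(net)[, c("protein_a", "protein_b")])
  expect_equal(sort(target_nodes(back)), "A")
})

test_that("score filtering keeps the threshold value and is idempotent", {
  rec <- data.frame(protein_a = c("A", "B", "C"), protein_b = c("X", "Y", "Z"),
                    combined_score = c(250L, 300L, 350L))
  expect_equal(nrow(filter_by_score(rec, 300)), 2L)  # "below 300" removed, 300 kept
  expect_equal(filter_by_score(rec, 0), rec)
  expect_equal(filter_by_score(filter_by_score(rec, 300), 300),
               filter_by_score(rec, 300))

  # brute-force recount on a synthetic score sample
  scores <- withr::with_seed(42, sample(150:999, 1000, replace = TRUE))
  rec2 <- data.frame(protein_a = sprintf("A%04d", 1:1000),
                     protein_b = sprintf("B%04d", 1:1000),
                     combined_score = scores)
  expect_equal(nrow(filter_by_score(rec2, 300)), sum(scores >= 300))
})

test_that("true-PPIN construction assigns roles and reports unmapped targets", {
  rec <- data.frame(protein_a = c("T1", "T1", "I1"), protein_b = c("I1", "I2", "I2"),
                    combined_score = c(500L, 500L, 500L))
  net <- build_true_ppin(rec, targets = "T1")
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 3L)
  expect_equal(target_nodes(net), "T1")
  expect_equal(sum(igraph::V(net)$role == "INTERACTOR"), 2L)

  expect_message(net2 <- build_true_ppin(rec, targets = "T9"), "absent")
  expect_equal(length(target_nodes(net2)), 0L)
  expect_equal(igraph::graph_attr(net2, "unmapped_targets"), "T9")

  expect_error(build_true_ppin(rec[0, ]), "no interaction records")
})

test_that("true-PPIN node and edge counts match a set-based recount", {
  g <- rgraph_edges(40, 0.2, seed = 11)
  rec <- data.frame(protein_a = g$edges$a, protein_b = g$edges$b,
                    combined_score = 500L)
  net <- build_true_ppin(rec, targets = g$nodes[1:5])
  expect_equal(igraph::vcount(net), length(unique(c(rec$protein_a, rec$protein_b))))
  expect_equal(igraph::ecount(net),
               length(unique(paste(pmin(rec$protein_a, rec$protein_b),
                                   pmax(rec$protein_a, rec$protein_b)))))
})

test_that("false-PPIN complement is exact on small graphs", {
  tri <- make_net(data.frame(a = c("T1", "T1", "I1"), b = c("I1", "I2", "I2")),
                  targets = "T1")
  expect_equal(igraph::ecount(build_false_ppin(tri, "all")), 0L)

  path <- make_net(data.frame(a = c("T1", "I1"), b = c("I1", "I2")), targets = "T1")
  fp <- build_false_ppin(path, "all")
  expect_equal(igraph::ecount(fp), 1L)
  expect_setequal(as.vector(igraph::as_edgelist(fp)), c("T1", "I2"))
})

test_that("false-PPIN edges are disjoint from true edges and count as the complement", {
  # brute-force enumeration on seeded graphs with <= 8 nodes
  for (s in 1:6) {
    g <- rgraph_edges(8, 0.4, seed = s)
    targets <- g$nodes[1:3]
    net <- make_net(g$edges, g$nodes, targets)
    fp <- build_false_ppin(net, "all")
    true_keys <- paste(pmin(g$edges$a, g$edges$b), pmax(g$edges$a, g$edges$b))
    fel <- igraph::as_edgelist(fp)
    false_keys <- if (nrow(fel)) paste(pmin(fel[, 1], fel[, 2]), pmax(fel[, 1], fel[, 2])) else character(0)
    expect_length(intersect(true_keys, false_keys), 0)
    # independent complement count: all target-incident unordered pairs
    all_pairs <- t(combn(g$nodes, 2))
    incident <- all_pairs[all_pairs[, 1] %in% targets | all_pairs[, 2] %in% targets, , drop = FALSE]
    inc_keys <- paste(pmin(incident[, 1], incident[, 2]), pmax(incident[, 1], incident[, 2]))
    expect_setequal(false_keys, setdiff(inc_keys, true_keys))
  }
})

test_that("false-PPIN sampling is seed-reproducible and avoids true edges", {
  g <- rgraph_edges(50, 0.1, seed = 99)
  net <- make_net(g$edges, g$nodes, targets = g$nodes[1:10])
  f1 <- build_false_ppin(net, 100, seed = 7)
  f2 <- build_false_ppin(net, 100, seed = 7)
  expect_equal(igraph::as_edgelist(f1), igraph::as_edgelist(f2))
  expect_equal(igraph::ecount(f1), 100L)
  true_keys <- paste(pmin(g$edges$a, g$edges$b), pmax(g$edges$a, g$edges$b))
  fel <- igraph::as_edgelist(f1)
  expect_length(intersect(paste(pmin(fel[, 1], fel[, 2]), pmax(fel[, 1], fel[, 2])),
                          true_keys), 0)
  expect_error(build_false_ppin(net, 10^6), "non-edges")
})

test_that("edge-list writer handles degenerate and large graphs", {
  tri <- make_net(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  f <- tempfile()
  write_edge_list(tri, f)
  expect_length(readLines(f), 4L)  # header + 3 edges

  empty <- make_net(data.frame(a = character(), b = character()),
                    nodes = c("X", "Y"))
  write_edge_list(empty, f)
  expect_length(readLines(f), 1L)
  expect_warning(back <- read_edge_list(f), "empty")
  expect_equal(igraph::vcount(back), 0L)

  g <- rgraph_edges(40, 0.25, seed = 5)
  net <- make_net(g$edges, g$nodes, targets = g$nodes[1:4])
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_equal(edge_pairs(back)[, 1:2], edge_pairs(net)[, 1:2])
  expect_setequal(target_nodes(back), target_nodes(net))
})
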