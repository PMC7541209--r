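test_that("centralities match analytic values on canonical graphs", {
  star <- make_net(data.frame(a = rep("C", 4), b = paste0("L", 1:4)))
  clo <- closeness_all(star)
  expect_equal(unname(clo["C"]), 1.0)
  expect_equal(unname(clo["L1"]), 4 / 7)  # distance sum 1+2+2+2

  path <- make_net(data.frame(a = c("A", "B"), b = c("B", "C")))
  btw <- betweenness_all(path)
  expect_equal(unname(btw[c("A", "B", "C")]), c(0, 1, 0))
  expect_equal(unname(eccentricity_all(path)[c("A", "B", "C")]), c(2, 1, 2))

  k4 <- make_net(as.data.frame(setNames(as.data.frame(t(combn(LETTERS[1:4], 2))),
                                        c("a", "b"))))
  expect_equal(unname(eigenvector_all(k4)), rep(0.5, 4))
  expect_equal(unname(betweenness_all(k4)), rep(0, 4))
  expect_equal(unname(clustering_coefficient_all(k4)), rep(1, 4))

  expect_equal(unname(clustering_coefficient_all(star)["C"]), 0)
  expect_equal(unname(degree_all(star)["C"]), 4)
})

test_that("disconnected graphs follow the component conventions", {
  # a triangle plus an isolated node
  g <- make_net(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")),
                nodes = c("A", "B", "C", "Z"))
  expect_equal(unname(closeness_all(g)["Z"]), 0)
  expect_equal(unname(eccentricity_all(g)["Z"]), 0)
  expect_equal(unname(clustering_coefficient_all(g)["Z"]), 0)
  # closeness of triangle members is component-scaled: (2/3) * (2/2)
  expect_equal(unname(closeness_all(g)["A"]), 2 / 3)

  # two disjoint equal edges: degenerate principal eigenvalue across components
  h <- make_net(data.frame(a = c("A", "X"), b = c("B", "Y")))
  expect_warning(ev <- eigenvector_all(h), "degenerate")
  expect_equal(sqrt(sum(ev^2)), 1)
  expect_equal(sum(ev > 0), 2L)  # supported on a single component

  expect_error(eigenvector_all(make_net(data.frame(a = character(), b = character()),
                                        nodes = "A")), "edge")
})

test_that("all six metrics agree with brute-force oracles on random graphs", {
  for (s in 1:8) {
    g <- rgraph_edges(30, 0.12, seed = s)
    net <- make_net(g$edges, g$nodes)
    expect_equal(degree_all(net)[g$nodes],
                 vapply(setNames(g$nodes, g$nodes), function(v) o_degree(g$edges, v),
                        numeric(1)))
    expect_equal(closeness_all(net)[g$nodes], o_closeness(g$edges, g$nodes),
                 tolerance = 1e-12)
    expect_equal(betweenness_all(net)[g$nodes], o_betweenness(g$edges, g$nodes),
                 tolerance = 1e-12)
    expect_equal(clustering_coefficient_all(net)[g$nodes],
                 o_clustering(g$edges, g$nodes), tolerance = 1e-12)
    expect_equal(as.numeric(eccentricity_all(net)[g$nodes]),
                 unname(o_eccentricity(g$edges, g$nodes)))
    expect_equal(sum(degree_all(net)), 2 * igraph::ecount(net))  # handshake
  }
  # eigenvector against a dense eigendecomposition (connected graphs)
  for (s in 1:4) {
    g <- rgraph_edges(20, 0.25, seed = s + 50, connected = TRUE)
    net <- make_net(g$edges, g$nodes)
    expect_equal(eigenvector_all(net, tol = 1e-10, max_iter = 1e5)[g$nodes],
                 o_eigenvector(g$edges, g$nodes), tolerance = 1e-6)
  }
})

test_that("metric values are invariant under node relabeling", {
  g <- rgraph_edges(15, 0.3, seed = 77)
  net <- make_net(g$edges, g$nodes)
  perm <- withr::with_seed(78, sample(g$nodes))
  relab <- setNames(perm, g$nodes)
  edges2 <- data.frame(a = unname(relab[g$edges$a]), b = unname(relab[g$edges$b]))
  net2 <- make_net(edges2, unname(relab[g$nodes]))
  for (f in list(degree_all, closeness_all, betweenness_all,
                 clustering_coefficient_all, eccentricity_all)) {
    expect_equal(unname(f(net)[g$nodes]), unname(f(net2)[relab[g$nodes]]),
                 tolerance = 1e-12)
  }
})

test_that("node-attribute table matches the per-metric operations", {
  star <- make_net(data.frame(a = rep("C", 4), b = paste0("L", 1:4)))
  tab <- node_attribute_table(star, "TRUE_NET")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$closeness[tab$node == "C"], 1.0)
  expect_equal(tab$degree[tab$node == "C"], 4L)
  expect_true(all(tab$origin == "TRUE_NET"))

  expect_equal(nrow(node_attribute_table(
    make_net(data.frame(a = character(), b = character()), nodes = character(0)),
    "TRUE_NET")), 0L)

  g <- rgraph_edges(40, 0.1, seed = 13)
  net <- make_net(g$edges, g$nodes)
  tab <- node_attribute_table(net, "FALSE_NET")
  expect_equal(tab$node, igraph::V(net)$name)
  expect_equal(tab$degree, unname(as.integer(degree_all(net))))
  expect_equal(tab$closeness, unname(closeness_all(net)))
  expect_equal(tab$eigenvector, unname(eigenvector_all(net)))
  expect_equal(tab$betweenness, unname(betweenness_all(net)))
  expect_equal(tab$clustering_coefficient, unname(clustering_coefficient_all(net)))
  expect_equal(tab$eccentricity, unname(as.integer(eccentricity_all(net))))
  # range invariants
  expect_true(all(tab$closeness >= 0 & tab$closeness <= 1))
  expect_true(all(tab$betweenness >= 0 & tab$betweenness <= 1))
  expect_true(all(tab$clustering_coefficient >= 0 & tab$clustering_coefficient <= 1))
  expect_true(all(tab$eccentricity <= igraph::vcount(net) - 1))
  expect_equal(sqrt(sum(tab$eigenvector^2)), 1)
})
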