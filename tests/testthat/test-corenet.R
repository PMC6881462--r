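star_graph <- function(leaves = 4) {
  igraph::graph_from_edgelist(
    cbind("hub", sprintf("leaf%d", seq_len(leaves))), directed = FALSE)
}

test_that("seed neighbourhood induces seeds plus direct neighbours", {
  g <- star_graph(4)
  sub <- seed_neighborhood(g, "hub")
  expect_equal(igraph::vcount(sub), 5)

  path <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("c", "d")), directed = FALSE)
  sub2 <- seed_neighborhood(path, "a")
  expect_setequal(igraph::V(sub2)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub2), 1)

  # isolated seed survives alone; unknown seeds warn
  g2 <- igraph::add_vertices(path, 1, name = "iso")
  sub3 <- seed_neighborhood(g2, "iso")
  expect_identical(igraph::V(sub3)$name, "iso")
  expect_warning(seed_neighborhood(path, c("a", "zz")), "not in the background")
  expect_error(suppressWarnings(seed_neighborhood(path, "zz")), "no seed")
})

test_that("steiner reduction keeps forced connectors and spans terminals", {
  # terminals = all nodes of a tree: the tree itself
  tree <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c"), c("b", "d")), directed = FALSE)
  red <- steiner_reduce(tree, c("a", "b", "c", "d"))
  expect_equal(igraph::ecount(red), 3)
  expect_setequal(igraph::V(red)$name, c("a", "b", "c", "d"))

  # star with 3 terminal leaves: the centre is a forced connector
  st <- star_graph(3)
  red2 <- steiner_reduce(st, sprintf("leaf%d", 1:3))
  expect_true("hub" %in% igraph::V(red2)$name)
  expect_equal(igraph::ecount(red2), 3)
  expect_false(igraph::vertex_attr(red2, "is_terminal",
                                   igraph::V(red2)["hub"]))
})

test_that("steiner output is an acyclic spanning forest with terminal leaves", {
  for (s in 1:40) {
    g <- random_connected_graph(sample(6:12, 1), runif(1, 0.2, 0.5), seed = s)
    terms <- sample(igraph::V(g)$name, sample(2:5, 1))
    red <- steiner_reduce(g, terms)
    expect_true(all(terms %in% igraph::V(red)$name))
    expect_equal(igraph::ecount(red), igraph::vcount(red) - 1)  # a tree
    deg <- igraph::degree(red)
    leaves <- names(deg)[deg <= 1]
    expect_true(all(leaves %in% terms))
    # deterministic
    red2 <- steiner_reduce(g, terms)
    expect_identical(igraph::as_edgelist(red), igraph::as_edgelist(red2))
  }
})

test_that("lncRNAs attach only through targets already inside the subnet", {
  tree <- igraph::graph_from_edgelist(
    rbind(c("a", "b"), c("b", "c")), directed = FALSE)
  pred <- data.frame(lncrna = c("L1", "L1", "L2"),
                     gene = c("a", "c", "zz"))
  out <- attach_delr_targets(tree, pred)
  expect_true("L1" %in% igraph::V(out)$name)
  expect_false("L2" %in% igraph::V(out)$name)
  expect_equal(igraph::degree(out, "L1"), c(L1 = 2))
  expect_identical(igraph::vertex_attr(out, "provenance",
                                       igraph::V(out)["L1"]), "delr")
  # empty prediction table leaves the subnet unchanged
  out0 <- attach_delr_targets(tree, pred[0, ])
  expect_equal(igraph::vcount(out0), 3)
})

test_that("largest component ties break on edges then node ids", {
  g <- igraph::graph_from_edgelist(
    rbind(c("a1", "a2"), c("a2", "a3"), c("a3", "a4"), c("a4", "a1"),
          c("b1", "b2"), c("b2", "b3"), c("b3", "b4")), directed = FALSE)
  lc <- largest_component(g)   # both 4 nodes; 4 edges beats 3
  expect_setequal(igraph::V(lc)$name, c("a1", "a2", "a3", "a4"))

  g2 <- igraph::graph_from_edgelist(
    rbind(c("z1", "z2"), c("z2", "z3"), c("a1", "a2"), c("a2", "a3")),
    directed = FALSE)
  lc2 <- largest_component(g2)  # equal size and edges; smallest id wins
  expect_setequal(igraph::V(lc2)$name, c("a1", "a2", "a3"))

  g3 <- star_graph(3)
  expect_equal(igraph::vcount(largest_component(g3)), igraph::vcount(g3))
})

test_that("degree ranking orders hubs first with lexicographic ties", {
  g <- star_graph(5)
  r <- degree_ranking(g)
  expect_identical(r$id[1], "hub")
  expect_equal(r$degree[1], 5)

  ring <- igraph::graph_from_edgelist(
    rbind(c("c", "a"), c("a", "b"), c("b", "c")), directed = FALSE)
  expect_identical(degree_ranking(ring)$id, c("a", "b", "c"))
  expect_equal(nrow(degree_ranking(g, top_k = 2)), 2)
})

test_that("a planted hub survives the whole core-network stage", {
  hits <- 0L
  for (s in 1:10) {
    d <- simulation_design(seed = s, n_genes = 150, n_lncrnas = 4,
                           planted_de = setNames(rep(4, 8),
                                                 sprintf("G%04d", 1:8)),
                           planted_cis_pairs = data.frame(lncrna = "L001",
                                                          gene = "G0001"),
                           hub_gene = "G0001",
                           network_modules = 4, module_size = 30)
    net <- generate_network(d)
    core <- suppressWarnings(build_core_network(
      net$graph, seeds = names(d$planted_de),
      predictions = data.frame(lncrna = "L001", gene = "G0001",
                               mode = "cis", evidence = 0),
      delrs = "L001"))
    rank <- degree_ranking(core, top_k = 5)
    if ("G0001" %in% rank$id) hits <- hits + 1L
    # the planted cis pair reaches the core whenever the hub is a seed
    expect_true(igraph::are_adjacent(core, "L001", "G0001"))
  }
  expect_gte(hits, 9L)
})
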