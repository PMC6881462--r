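kgml_file <- function(entries, relations) {
  path <- tempfile(fileext = ".xml")
  ent <- paste(sprintf('<entry id="%s" name="%s" type="gene"/>',
                       names(entries), vapply(entries, paste,
                                              character(1), collapse = " ")),
               collapse = "\n")
  rel <- paste(sprintf('<relation entry1="%s" entry2="%s" type="PPrel"/>',
                       relations[, 1], relations[, 2]), collapse = "\n")
  writeLines(sprintf("<pathway>\n%s\n%s\n</pathway>", ent, rel), path)
  path
}

test_that("background construction dedupes, drops loops and expands entries", {
  f1 <- kgml_file(list(e1 = "a", e2 = "b"),
                  rbind(c("e1", "e2"), c("e2", "e1"), c("e1", "e1")))
  g <- build_background(f1)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("a", "b"))

  # union across files keeps a shared edge once
  f2 <- kgml_file(list(e1 = "a", e2 = "b", e3 = "c"),
                  rbind(c("e1", "e2"), c("e2", "e3")))
  g2 <- build_background(c(f1, f2))
  expect_equal(igraph::ecount(g2), 2)

  # multi-id entries expand to all endpoint combinations
  f3 <- kgml_file(list(e1 = c("g1", "g2"), e2 = "g3"),
                  rbind(c("e1", "e2")))
  g3 <- build_background(f3)
  el <- apply(igraph::as_edgelist(g3), 1, function(r)
    paste(sort(r), collapse = "-"))
  expect_setequal(el, c("g1-g3", "g2-g3"))

  # plain edge lists mix in
  f4 <- tempfile(fileext = ".tsv")
  writeLines("g3\tg4", f4)
  g4 <- build_background(c(f3, f4))
  expect_equal(igraph::ecount(g4), 3)
})

test_that("pairwise distances follow BFS hops and report connectivity", {
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                   directed = FALSE)
  res <- pairwise_distances(g, "a", "c")
  expect_identical(res$distances, 2)
  expect_equal(res$connectivity, 1)

  # two components: no path, mean undefined
  g2 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("x", "y")),
                                    directed = FALSE)
  res2 <- pairwise_distances(g2, c("a", "b"), c("x", "y"))
  expect_equal(res2$connectivity, 0)
  expect_true(is.na(res2$mean_distance))

  # symmetry in the arguments
  set.seed(2)
  g3 <- random_connected_graph(15, 0.2, seed = 2)
  nm <- igraph::V(g3)$name
  a <- nm[1:4]; b <- nm[8:12]
  expect_identical(sort(pairwise_distances(g3, a, b)$distances),
                   sort(pairwise_distances(g3, b, a)$distances))
  # a set within one component reaches itself completely
  expect_equal(pairwise_distances(g3, a, a)$connectivity, 1)
})

test_that("distances match the Floyd-Warshall oracle on random graphs", {
  for (s in 1:25) {
    g <- random_connected_graph(sample(8:30, 1), runif(1, 0.1, 0.3), seed = s)
    nm <- igraph::V(g)$name
    a <- sample(nm, 4); b <- sample(nm, 6)
    fw <- floyd_warshall(g)
    expected <- as.numeric(fw[a, b][outer(a, b, "!=")])
    got <- pairwise_distances(g, a, b)$distances
    expect_identical(sort(got), sort(expected))
  }
})

test_that("adding an edge never increases a distance", {
  for (s in 1:10) {
    g <- random_connected_graph(12, 0.2, seed = 100 + s)
    nm <- igraph::V(g)$name
    d0 <- floyd_warshall(g)
    non_edges <- which(as.matrix(igraph::as_adjacency_matrix(g)) == 0 &
                         upper.tri(d0), arr.ind = TRUE)
    pick <- non_edges[sample(nrow(non_edges), 1), ]
    g2 <- igraph::add_edges(g, nm[pick])
    d1 <- floyd_warshall(g2)
    expect_true(all(d1 <= d0 + 1e-9))
  }
})

test_that("proximity contrast is null for symmetric sets and detects bias", {
  # 4-cycle: both probes sit one hop from the reference
  g <- igraph::graph_from_edgelist(
    rbind(c("n1", "n2"), c("n2", "n3"), c("n3", "n4"), c("n4", "n1")),
    directed = FALSE)
  pc <- proximity_contrast(g, "n1", "n2", "n4")
  expect_equal(pc$ks_stat, 0)
  expect_equal(pc$ks_p, 1)
  expect_error(proximity_contrast(g, "n1", "n2", "n2"), "disjoint")

  # planted module bias shortens distances to the reference set
  wins <- 0L
  for (s in 1:10) {
    d <- simulation_design(seed = s, n_genes = 150, n_lncrnas = 2,
                           planted_de = setNames(rep(4, 8),
                                                 sprintf("G%04d", 1:8)),
                           hub_gene = "G0001",
                           network_modules = 4, module_size = 30,
                           nei_size = 15, nei_bias = 0.8)
    net <- generate_network(d)
    nm <- igraph::V(net$graph)$name
    x <- intersect(names(d$planted_de), nm)
    xbar <- setdiff(nm, c(x, net$nei))
    pc <- suppressMessages(proximity_contrast(net$graph, net$nei, x, xbar))
    if (pc$x$mean_distance < pc$xbar$mean_distance && pc$ks_p < 0.05)
      wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the asymptotic KS p agrees with a permutation oracle on untied data", {
  set.seed(3)
  a <- rnorm(80); b <- rnorm(120, 0.3)
  obs <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  comb <- c(a, b); n1 <- length(a)
  set.seed(4)
  perm <- replicate(2000, {
    i <- sample(length(comb))
    suppressWarnings(stats::ks.test(comb[i[1:n1]], comb[i[-(1:n1)]],
                                    exact = FALSE)$statistic)
  })
  expect_equal(obs$p.value, mean(perm >= obs$statistic - 1e-12),
               tolerance = 0.03)
})
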