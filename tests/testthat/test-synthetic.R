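test_that("designs are validated against their universe and probabilities", {
  expect_error(simulation_design(n_case = 1), "samples per group")
  expect_error(simulation_design(planted_de = c(ZZZ = 4),
                                 n_genes = 10, network_modules = 2,
                                 module_size = 2), "universe")
  expect_error(simulation_design(planted_de = c(G0001 = 0.5), n_genes = 10,
                                 network_modules = 2, module_size = 2),
               "FC")
  expect_error(simulation_design(p_in = 0.01, p_out = 0.1, n_genes = 10,
                                 network_modules = 2, module_size = 2),
               "exceed")
  expect_error(simulation_design(n_genes = 5, network_modules = 4,
                                 module_size = 30), "larger than")
})

test_that("zero-noise generation forces exact downstream estimates", {
  fx <- toy_planted_matrix()
  expect_equal(log_fold_change(fx$sim$gene, "G0001"), 2)
  for (g in c("G0002", "G0003", "L001"))
    expect_equal(log_fold_change(fx$sim$gene, g), 0)
  # empty planting: everything flat
  d0 <- simulation_design(seed = 2, n_genes = 5, n_lncrnas = 2,
                          noise_sd = 0, network_modules = 2, module_size = 2,
                          nei_size = 2)
  sim0 <- generate_expression(d0)
  for (g in d0$gene_ids)
    expect_equal(log_fold_change(sim0$gene, g), 0)
})

test_that("generators are pure functions of the design", {
  d <- simulation_design(seed = 42, n_genes = 30, n_lncrnas = 4,
                         planted_de = c(G0001 = 4),
                         network_modules = 2, module_size = 10,
                         nei_size = 4)
  e1 <- generate_expression(d); e2 <- generate_expression(d)
  expect_identical(e1$gene$intensity, e2$gene$intensity)
  expect_identical(e1$exon$intensity, e2$exon$intensity)
  a1 <- generate_annotation(d); a2 <- generate_annotation(d)
  expect_identical(a1, a2)
  n1 <- generate_network(d); n2 <- generate_network(d)
  expect_identical(igraph::as_edgelist(n1$graph),
                   igraph::as_edgelist(n2$graph))
  expect_identical(n1$nei, n2$nei)
})

test_that("exon counts, planted events and window geometry honour the design", {
  d <- simulation_design(seed = 3, n_genes = 40, n_lncrnas = 5,
                         planted_splice = data.frame(gene = "G0005",
                                                     label = "cassette exon",
                                                     magnitude = 4,
                                                     exon_index = NA),
                         planted_cis_pairs = data.frame(
                           lncrna = c("L001", "L002"),
                           gene = c("G0007", "G0007")),
                         noise_sd = 0,
                         network_modules = 2, module_size = 10, nei_size = 3)
  sim <- generate_expression(d)
  counts <- table(sim$exon$gene_id)
  expect_true(all(counts >= 4 & counts <= 10))
  tr <- sim$truth$splice
  expect_identical(tr$gene, "G0005")
  expect_gte(tr$exon_index, 2)                  # interior by construction
  expect_lt(tr$exon_index, counts[["G0005"]])
  # both planted lncRNAs overlap the shared partner gene's window
  anno <- generate_annotation(d)
  res <- predict_cis(anno)
  expect_setequal(paste(res$lncrna, res$gene),
                  c("L001 G0007", "L002 G0007"))
})

test_that("the planted-partition network honours its edge probabilities", {
  d <- simulation_design(seed = 8, n_genes = 40, n_lncrnas = 2,
                         network_modules = 4, module_size = 8,
                         p_in = 0.4, p_out = 0.02, nei_size = 4)
  # boundary case: no between-module edges at all
  d0 <- simulation_design(seed = 8, n_genes = 40, n_lncrnas = 2,
                          network_modules = 4, module_size = 8,
                          p_in = 0.4, p_out = 0, nei_size = 4)
  net0 <- generate_network(d0, connect = FALSE)
  expect_equal(igraph::components(net0$graph)$no, 4)
  # within-module cliques when p_in = 1
  d1 <- simulation_design(seed = 8, n_genes = 40, n_lncrnas = 2,
                          network_modules = 4, module_size = 8,
                          p_in = 1, p_out = 0, nei_size = 4)
  net1 <- generate_network(d1, connect = FALSE)
  m1 <- names(net1$membership)[net1$membership == 1]
  sub <- igraph::induced_subgraph(net1$graph, m1)
  expect_equal(igraph::ecount(sub), choose(length(m1), 2))
  # the patched graph is connected
  net <- generate_network(d)
  expect_equal(igraph::components(net$graph)$no, 1)
  # the reference set is biased into the hub module
  d2 <- simulation_design(seed = 8, n_genes = 40, n_lncrnas = 2,
                          network_modules = 4, module_size = 8,
                          hub_gene = "G0001", nei_size = 12, nei_bias = 0.9)
  net2 <- generate_network(d2)
  in_mod1 <- mean(net2$nei %in% names(net2$membership)[net2$membership == 1])
  expect_gt(in_mod1, 0.5)
})

test_that("a dataset on disk round-trips through the readers", {
  dir <- tempfile("ds")
  d <- simulation_design(seed = 6, n_genes = 30, n_lncrnas = 4,
                         planted_de = c(G0001 = 4),
                         network_modules = 2, module_size = 10, nei_size = 3)
  cfg <- write_dataset(d, dir)
  expect_true(all(file.exists(unlist(cfg[c("expression", "exons",
                                           "annotation", "pathways",
                                           "network", "nei", "qpcr")]))))
  sim <- generate_expression(d)
  back <- read_expression_tsv(cfg$expression)
  expect_equal(back$intensity, sim$gene$intensity, tolerance = 1e-8)
  expect_identical(as.character(back$groups), as.character(sim$gene$groups))
  exons <- read_expression_tsv(cfg$exons, exon = TRUE)
  expect_identical(exons$gene_id, sim$exon$gene_id)
  anno <- read_annotation(cfg$annotation)
  expect_setequal(anno$id, c(d$gene_ids, d$lnc_ids))
  expect_identical(sort(unique(anno$biotype)), c("coding", "lncRNA"))
  gmt <- read_gmt(cfg$pathways)
  expect_length(gmt, d$n_pathways)
})
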