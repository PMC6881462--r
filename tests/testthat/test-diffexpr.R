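test_that("tukey biweight recovers the centre of clean and contaminated data", {
  expect_identical(tukey_biweight(c(5, 5, 5, 5)), 5)
  expect_equal(tukey_biweight(c(1, 2, 3)), 2)
  # a gross outlier gets weight zero (its u exceeds 1); the arithmetic
  # mean of the same data would be 20.8
  bw <- tukey_biweight(c(1, 1, 1, 1, 100))
  expect_gte(bw, 1); expect_lte(bw, 1.05)
  expect_error(tukey_biweight(numeric()))
})

test_that("biweight is location/scale-equivariant and stays inside the range", {
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(11, sd = 2)
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    expect_equal(tukey_biweight(a * x + b), a * tukey_biweight(x) + b,
                 tolerance = 1e-5)
    expect_gte(tukey_biweight(x), min(x))
    expect_lte(tukey_biweight(x), max(x))
  }
})

test_that("log fold change follows the biweight-ratio definition", {
  m <- expression_matrix(
    matrix(c(rep(256, 3), rep(64, 3)), nrow = 1,
           dimnames = list("g", paste0("s", 1:6))),
    rep(c("case", "control"), each = 3))
  expect_equal(log_fold_change(m, "g"), 2)

  m2 <- expression_matrix(
    matrix(rep(50, 6), nrow = 1, dimnames = list("g", paste0("s", 1:6))),
    rep(c("case", "control"), each = 3))
  expect_equal(log_fold_change(m2, "g"), 0)

  # swapping group labels flips the sign; common scaling cancels
  set.seed(1)
  v <- runif(6, 10, 100)
  mk <- function(vals, grp) expression_matrix(
    matrix(vals, nrow = 1, dimnames = list("g", paste0("s", 1:6))), grp)
  grp <- rep(c("case", "control"), each = 3)
  expect_equal(log_fold_change(mk(v, grp), "g"),
               -log_fold_change(mk(v, rev(grp)), "g"))
  # equal up to the epsilon stabiliser in the biweight scale
  expect_equal(log_fold_change(mk(v, grp), "g"),
               log_fold_change(mk(7 * v, grp), "g"), tolerance = 1e-5)
})

test_that("one-way ANOVA p matches the F decomposition and the t-test", {
  # SSbetween = 13.5, SSwithin = 4, df (1, 4): F = 13.5
  expect_equal(anova_p(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3)),
               pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # equal means, unequal spread
  expect_equal(anova_p(c(1, 3, 0, 4), c("a", "a", "b", "b")), 1)
  # zero within-group variance convention
  expect_equal(anova_p(c(1, 1, 2, 2), c("a", "a", "b", "b")), 0)
  expect_equal(anova_p(c(2, 2, 2, 2), c("a", "a", "b", "b")), 1)
  # t^2 = F identity on random draws
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(5); y <- rnorm(7, 0.5)
    expect_equal(anova_p(c(x, y), rep(c("a", "b"), c(5, 7))),
                 t.test(x, y, var.equal = TRUE)$p.value, tolerance = 1e-10)
  }
})

test_that("call_de recovers a planted zero-noise signal and nothing else", {
  fx <- toy_planted_matrix()
  de <- call_de(fx$sim$gene, fx$anno)
  expect_identical(de$id[de$is_de], "G0001")
  expect_equal(de$logFC[de$id == "G0001"], 2)
  expect_equal(de$signedFC[de$id == "G0001"], 4)
  expect_true(all(abs(de$logFC[de$id != "G0001"]) < 1e-12))
  # impossible thresholds produce no calls
  de0 <- call_de(fx$sim$gene, fx$anno, fc_threshold = Inf, p_threshold = 0)
  expect_false(any(de0$is_de))
  # classes split by biotype
  cls <- de_classes(de)
  expect_identical(cls$deg, "G0001")
  expect_identical(cls$delr, character(0))
})

test_that("signed linear FC convention mirrors logFC", {
  fx <- toy_planted_matrix()
  de <- call_de(fx$sim$gene, fx$anno)
  expect_equal(de$signedFC,
               ifelse(de$logFC >= 0, 2^de$logFC, -2^(-de$logFC)))
})

test_that("call_de is monotone in the fold-change threshold", {
  d <- simulation_design(seed = 3, n_genes = 40, n_lncrnas = 2,
                         planted_de = setNames(c(4, -4, 2), sprintf("G%04d", 1:3)),
                         noise_sd = 0.4, network_modules = 2, module_size = 5,
                         nei_size = 2)
  sim <- generate_expression(d)
  anno <- generate_annotation(d)
  prev <- character()
  for (fc in c(2.5, 2, 1.5, 1, 0.5)) {
    de <- call_de(sim$gene, anno, fc_threshold = fc)
    called <- de$id[de$is_de]
    expect_true(all(prev %in% called))
    prev <- called
  }
})

test_that("features missing from the annotation are excluded with a warning", {
  fx <- toy_planted_matrix()
  anno <- fx$anno[fx$anno$id != "G0002", ]
  expect_warning(de <- call_de(fx$sim$gene, anno), "missing from annotation")
  expect_false("G0002" %in% de$id)
  expect_identical(attr(de, "excluded"), "G0002")
})
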