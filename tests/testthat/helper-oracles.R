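# Independent oracles used to cross-check the package's own algorithms.
# Everything here is deliberately naive (enumeration, dense matrices,
# textbook recurrences) and shares no code with the implementation.

# random connected graph with named nodes: G(n, p) patched to connectivity
# by a random spanning path
random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  perm <- sample(n)
  for (i in seq_len(n - 1L))
    g <- igraph::add_edges(g, c(perm[i], perm[i + 1L]))
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Floyd-Warshall all-pairs shortest paths on the unweighted adjacency matrix
floyd_warshall <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# exact minimal Steiner tree cost for unit edge weights: with unit weights
# the optimum tree minimises node count, so enumerate subsets of
# non-terminals by increasing size and return the first connecting one
exact_steiner_cost <- function(g, terminals) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  nm <- rownames(a)
  tidx <- match(terminals, nm)
  rest <- setdiff(seq_along(nm), tidx)
  connected <- function(idx) {
    if (length(idx) == 1L) return(TRUE)
    sub <- a[idx, idx, drop = FALSE]
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
      nxt <- setdiff(which(colSums(sub[frontier, , drop = FALSE]) > 0), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(idx)
  }
  for (k in 0:length(rest)) {
    subsets <- if (k == 0L) list(integer()) else
      asplit(utils::combn(rest, k), 2L)
    for (s in subsets)
      if (connected(c(tidx, s))) return(length(tidx) + k - 1L)
  }
  stop("terminals not connectable")
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
# (pathway = the first K elements of 1..N)
hyper_enum <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  succ <- if (n == 0L) 0L else colSums(draws <= K)
  mean(succ >= k)
}

# modularity by the per-pair definition, independent of edge bookkeeping
modularity_oracle <- function(g, memb) {
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  deg <- rowSums(a)
  m2 <- sum(deg)
  s <- outer(memb, memb, "==")
  sum(((a - outer(deg, deg) / m2) * s)) / m2
}

# maximum modularity by enumerating all set partitions (restricted growth
# strings); feasible up to ~10 nodes
max_modularity_enum <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  rgs <- integer(n)
  recurse <- function(i, maxlab) {
    if (i > n) {
      q <- modularity_oracle(g, rgs[1:n])
      if (q > best) best <<- q
      return(invisible())
    }
    for (lab in 1:(maxlab + 1L)) {
      rgs[i] <<- lab
      recurse(i + 1L, max(maxlab, lab))
    }
  }
  recurse(1L, 0L)
  best
}

# AUC by explicit ROC-curve construction and trapezoidal integration
trapezoid_auc <- function(values, pos) {
  thr <- c(Inf, sort(unique(values), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(values[pos] >= t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(values[!pos] >= t), numeric(1L))
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

# ring of k cliques (K`size` each) with single bridge edges, named nodes
ring_of_cliques <- function(k = 4L, size = 6L) {
  el <- NULL
  node <- function(m, i) sprintf("m%d_%d", m, i)
  for (m in seq_len(k)) {
    pairs <- utils::combn(size, 2L)
    el <- rbind(el, cbind(node(m, pairs[1L, ]), node(m, pairs[2L, ])))
  }
  for (m in seq_len(k))
    el <- rbind(el, cbind(node(m, 1L), node(m %% k + 1L, 2L)))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# zero-noise two-group expression fixture with one planted logFC-2 gene
toy_planted_matrix <- function() {
  d <- simulation_design(seed = 1, n_genes = 5, n_lncrnas = 2,
                         planted_de = c(G0001 = 4), noise_sd = 0,
                         network_modules = 2, module_size = 2,
                         nei_size = 2)
  list(design = d, sim = generate_expression(d),
       anno = generate_annotation(d))
}
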