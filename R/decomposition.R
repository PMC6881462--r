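#' Newman-Girvan modularity of a partition
#'
#' `Q = sum_s [ e_s / m - (d_s / 2m)^2 ]` where `m` is the edge count,
#' `e_s` the number of edges inside module `s` and `d_s` the total degree
#' of its nodes. Computed by direct edge counting.
#'
#' @param g igraph undirected graph.
#' @param membership module id per vertex (any labels; coerced to integer
#'   codes), in vertex order.
#' @return Q.
#' @export
modularity_q <- function(g, membership) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  if (length(membership) != n) stop("membership must cover all nodes")
  memb <- as.integer(as.factor(membership))
  m <- igraph::ecount(g)
  if (m == 0L) stop("graph has no edges")
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  e_s <- tapply(memb[el[, 1L]] == memb[el[, 2L]], memb[el[, 1L]], sum)
  within <- numeric(max(memb))
  within[as.integer(names(e_s))] <- e_s
  d_s <- tapply(deg, memb, sum)
  dtot <- numeric(max(memb))
  dtot[as.integer(names(d_s))] <- d_s
  sum(within / m - (dtot / (2 * m))^2)
}

#' Decompose a network into modules by simulated annealing
#'
#' Stochastic maximisation of modularity Q over partitions. The move set
#' mixes single-node reassignments (including moves into a fresh module),
#' pairwise module merges and random bipartition splits; a move with
#' `dQ > 0` is always accepted, otherwise with probability `exp(dQ / T)`.
#' Temperature follows a geometric schedule. The best partition seen is
#' returned, with Q recomputed from scratch as a cross-check.
#'
#' @param g connected igraph graph with >= 2 nodes.
#' @param t0 initial temperature (> 0).
#' @param cooling geometric cooling factor in (0, 1).
#' @param steps_per_t proposals per temperature level; default `vcount^2`.
#' @param t_min stop when the temperature falls below this.
#' @param seed integer seed driving the stochastic search; same seed and
#'   schedule give an identical partition.
#' @return object of class `module_partition`: list with `membership`
#'   (named integer vector, consecutive module ids starting at 1), `q`,
#'   `n_modules`, `trace` (data frame `temperature`, `q` per accepted
#'   move), `seed`.
#' @export
anneal_partition <- function(g, t0 = 1, cooling = 0.95, steps_per_t = NULL,
                             t_min = 1e-4, seed = 1L) {
  if (t0 <= 0 || cooling <= 0 || cooling >= 1)
    stop("invalid schedule: need t0 > 0 and cooling in (0, 1)")
  n <- igraph::vcount(g)
  if (n < 2L) stop("need >= 2 nodes")
  if (igraph::components(g)$no != 1L)
    stop("graph must be connected")
  if (is.null(steps_per_t)) steps_per_t <- n^2
  el <- igraph::as_edgelist(g, names = FALSE)
  set.seed(as.integer(seed))
  res <- anneal_cpp(n, el - 1L, as.numeric(t0), as.numeric(cooling),
                    as.integer(steps_per_t), as.numeric(t_min))
  memb <- as.integer(as.factor(res$membership))
  names(memb) <- igraph::V(g)$name
  q <- modularity_q(g, memb)
  if (abs(q - res$q) > 1e-9)
    stop("internal error: annealer Q does not recompute")   # nocov
  structure(list(membership = memb, q = q,
                 n_modules = length(unique(memb)),
                 trace = data.frame(temperature = res$trace_t,
                                    q = res$trace_q),
                 seed = as.integer(seed)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes in %d modules, Q = %.4f (seed %d)\n",
              length(x$membership), x$n_modules, x$q, x$seed))
  invisible(x)
}

#' Share of inter-module edges touching a module subset
#'
#' Fraction of the edges that run between different modules which have at
#' least one endpoint inside the given modules. Used to quantify how much
#' of the cross-talk between modules a hub module carries.
#'
#' @param g igraph graph.
#' @param membership module id per vertex (vertex order).
#' @param modules module ids forming the subset.
#' @return fraction in `[0, 1]`; `NA` (with a message) when the partition
#'   has no inter-module edges.
#' @export
inter_module_share <- function(g, membership, modules) {
  memb <- membership
  if (length(memb) != igraph::vcount(g)) stop("membership must cover all nodes")
  el <- igraph::as_edgelist(g, names = FALSE)
  m1 <- memb[el[, 1L]]; m2 <- memb[el[, 2L]]
  inter <- m1 != m2
  if (!any(inter)) {
    message("partition has no inter-module edges; share undefined")
    return(NA_real_)
  }
  touched <- inter & (m1 %in% modules | m2 %in% modules)
  sum(touched) / sum(inter)
}

#' Label modules by their top enriched pathway
#'
#' Runs [enrich()] for each module's gene set against a GMT collection and
#' labels the module with its minimum-p pathway. Modules with no gene in
#' the background are labelled `"unannotated"`.
#'
#' @param membership named module id per gene (names are gene ids).
#' @param gene_sets named list of pathways.
#' @param background gene universe (default: union of all pathways and the
#'   partition's genes).
#' @return data frame `module`, `size`, `label`, `p`.
#' @export
module_function_labels <- function(membership, gene_sets,
                                   background = NULL) {
  if (is.null(background))
    background <- union(unlist(gene_sets), names(membership))
  rows <- lapply(sort(unique(membership)), function(mod) {
    genes <- names(membership)[membership == mod]
    inbg <- intersect(genes, background)
    if (length(inbg) == 0L)
      return(data.frame(module = mod, size = length(genes),
                        label = "unannotated", p = NA_real_,
                        stringsAsFactors = FALSE))
    res <- tryCatch(suppressMessages(enrich(inbg, gene_sets, background)),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res) == 0L || all(res$k == 0))
      return(data.frame(module = mod, size = length(genes),
                        label = "unannotated", p = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(module = mod, size = length(genes),
               label = res$pathway[1L], p = res$p[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
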