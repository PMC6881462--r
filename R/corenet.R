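## Deterministic BFS helpers used by the Steiner reduction. Neighbours are
## visited in lexicographic order so that path reconstruction (smallest
## predecessor at each hop) is reproducible across platforms.

sorted_adj <- function(g) {
  nm <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g, mode = "all")
  lapply(adj, function(v) sort(nm[as.integer(v)]))
}

bfs_dist <- function(adj, from) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) if (!is.finite(d[w])) {
      d[w] <- d[v] + 1
      queue <- c(queue, w)
    }
  }
  d
}

## Shortest path from..to; ties broken by taking the lexicographically
## smallest predecessor at every hop (walking back from `to`).
bfs_path <- function(adj, d_from, from, to) {
  if (!is.finite(d_from[to])) return(NULL)
  path <- to
  v <- to
  while (v != from) {
    preds <- adj[[v]][d_from[adj[[v]]] == d_from[v] - 1]
    v <- min(preds)
    path <- c(v, path)
  }
  path
}

## Prim's MST with deterministic tie-breaks: smallest weight, then
## lexicographically smallest (from, to) pair. `w` is a symmetric matrix
## with dimnames; Inf marks absent edges.
prim_mst <- function(w) {
  nodes <- sort(rownames(w))
  if (length(nodes) == 1L)
    return(matrix(character(), ncol = 2L))
  in_tree <- nodes[1L]
  rest <- setdiff(nodes, in_tree)
  edges <- matrix(character(), ncol = 2L)
  while (length(rest)) {
    best <- NULL; best_w <- Inf
    for (u in in_tree) for (v in rest) {
      if (w[u, v] < best_w ||
          (w[u, v] == best_w && !is.null(best) &&
           (u < best[1L] || (u == best[1L] && v < best[2L])))) {
        best <- c(u, v); best_w <- w[u, v]
      }
    }
    if (!is.finite(best_w)) stop("graph not connected in prim_mst")
    edges <- rbind(edges, best)
    in_tree <- c(in_tree, best[2L])
    rest <- setdiff(rest, best[2L])
  }
  unname(edges)
}

#' Seed neighbourhood subnetwork
#'
#' Induced subgraph on the seed genes and all their direct neighbours in
#' the background network. Seeds absent from the network are dropped with a
#' warning.
#'
#' @param g igraph background network with named vertices.
#' @param seeds character vector of seed gene ids.
#' @return igraph subgraph.
#' @export
seed_neighborhood <- function(g, seeds) {
  nm <- igraph::V(g)$name
  missing <- setdiff(seeds, nm)
  if (length(missing))
    warning(length(missing), " seed(s) not in the background network: ",
            paste(utils::head(missing, 5L), collapse = ", "))
  seeds <- intersect(seeds, nm)
  if (length(seeds) == 0L) stop("no seed maps into the network")
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(g, seeds), function(v) nm[as.integer(v)])))
  igraph::induced_subgraph(g, vids = union(seeds, nbrs))
}

#' Steiner-minimal-tree reduction of a subnetwork
#'
#' 2-approximate Steiner minimal tree over unit edge weights via the
#' classical metric-closure construction: complete graph on the terminals
#' weighted by shortest-path hops, minimum spanning tree of that closure,
#' expansion of its edges into shortest paths, minimum spanning tree of the
#' expanded subgraph, then iterative pruning of non-terminal leaves. All
#' tie-breaks are lexicographic on node id, so the result is deterministic.
#' Components of the subnetwork are reduced independently; the result is a
#' forest when terminals span several components.
#'
#' @param g igraph subnetwork with named vertices.
#' @param terminals character vector of terminal (seed) node ids present in
#'   `g`.
#' @return igraph forest containing every terminal; non-terminal nodes that
#'   survive are the Steiner connectors (vertex attribute `is_terminal`).
#' @export
steiner_reduce <- function(g, terminals) {
  nm <- igraph::V(g)$name
  terminals <- intersect(terminals, nm)
  if (length(terminals) == 0L) stop("no terminal present in the subnetwork")
  comp <- igraph::components(g)
  keep_edges <- matrix(character(), ncol = 2L)
  keep_nodes <- character()
  for (ci in seq_len(comp$no)) {
    members <- nm[comp$membership == ci]
    term_c <- sort(intersect(terminals, members))
    if (length(term_c) == 0L) next
    keep_nodes <- c(keep_nodes, term_c)
    if (length(term_c) == 1L) next
    sub <- igraph::induced_subgraph(g, vids = members)
    adj <- sorted_adj(sub)
    dmat <- do.call(rbind, lapply(term_c, function(t) bfs_dist(adj, t)))
    rownames(dmat) <- term_c
    closure <- dmat[, term_c, drop = FALSE]
    mst1 <- prim_mst(closure)
    ## expand closure edges into concrete shortest paths
    path_edges <- matrix(character(), ncol = 2L)
    for (i in seq_len(nrow(mst1))) {
      p <- bfs_path(adj, dmat[mst1[i, 1L], ], mst1[i, 1L], mst1[i, 2L])
      if (length(p) > 1L)
        path_edges <- rbind(path_edges, cbind(p[-length(p)], p[-1L]))
    }
    nodes <- sort(unique(as.vector(path_edges)))
    ## MST of the expanded subgraph (unit weights, deterministic)
    w <- matrix(Inf, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    for (i in seq_len(nrow(path_edges)))
      w[path_edges[i, 1L], path_edges[i, 2L]] <-
        w[path_edges[i, 2L], path_edges[i, 1L]] <- 1
    mst2 <- prim_mst(w)
    ## prune non-terminal leaves
    repeat {
      degs <- table(factor(as.vector(mst2), levels = nodes))
      leaves <- names(degs)[degs == 1L & !(names(degs) %in% term_c)]
      if (length(leaves) == 0L) break
      drop <- mst2[, 1L] %in% leaves | mst2[, 2L] %in% leaves
      mst2 <- mst2[!drop, , drop = FALSE]
      nodes <- setdiff(nodes, leaves)
    }
    keep_edges <- rbind(keep_edges, mst2)
    keep_nodes <- c(keep_nodes, nodes)
  }
  out <- if (nrow(keep_edges))
    igraph::graph_from_edgelist(keep_edges, directed = FALSE)
  else igraph::make_empty_graph(directed = FALSE)
  iso <- setdiff(unique(keep_nodes), igraph::V(out)$name)
  if (length(iso)) out <- igraph::add_vertices(out, length(iso), name = iso)
  igraph::set_vertex_attr(out, "is_terminal",
                          value = igraph::V(out)$name %in% terminals)
}

#' Attach differentially expressed lncRNAs to their targets in a subnetwork
#'
#' Each lncRNA with at least one predicted target already inside the
#' reduced subnetwork is added as a new node with an edge to each such
#' target. lncRNAs whose targets all fall outside are not added; their
#' predictions are ignored (and counted in `attr(, "ignored")`). New nodes
#' get `provenance = "delr"`, new edges `provenance = "delr-target"`.
#'
#' @param tree igraph subnetwork (e.g. from [steiner_reduce()]).
#' @param predictions data frame with columns `lncrna`, `gene` (e.g. from
#'   [predict_cis()] / [predict_trans()]).
#' @param delrs lncRNA ids to attach (default: all in `predictions`).
#' @return igraph graph with provenance attributes on nodes and edges.
#' @export
attach_delr_targets <- function(tree, predictions, delrs = NULL) {
  g <- tree
  if (is.null(igraph::vertex_attr(g, "provenance")))
    g <- igraph::set_vertex_attr(g, "provenance", value = "background")
  if (igraph::ecount(g) > 0 && is.null(igraph::edge_attr(g, "provenance")))
    g <- igraph::set_edge_attr(g, "provenance", value = "background")
  if (is.null(delrs)) delrs <- unique(predictions$lncrna)
  ignored <- 0L
  for (l in sort(unique(delrs))) {
    tg <- sort(unique(predictions$gene[predictions$lncrna == l]))
    inside <- intersect(tg, igraph::V(g)$name)
    ignored <- ignored + length(tg) - length(inside)
    if (length(inside) == 0L) next
    g <- igraph::add_vertices(g, 1L, name = l, provenance = "delr")
    for (t in inside)
      g <- igraph::add_edges(g, c(l, t), provenance = "delr-target")
  }
  attr(g, "ignored") <- ignored
  g
}

#' Largest connected component
#'
#' Ties on node count are broken by edge count, then by the
#' lexicographically smallest member node id.
#'
#' @param g igraph graph.
#' @return igraph subgraph, the winning component.
#' @export
largest_component <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  nm <- igraph::V(g)$name
  stats <- lapply(seq_len(comp$no), function(ci) {
    members <- nm[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vids = members)
    list(ci = ci, n = length(members), m = igraph::ecount(sub),
         lo = min(members))
  })
  ord <- order(-vapply(stats, `[[`, numeric(1), "n"),
               -vapply(stats, `[[`, numeric(1), "m"),
               vapply(stats, `[[`, character(1), "lo"))
  win <- stats[[ord[1L]]]
  igraph::induced_subgraph(g, vids = nm[comp$membership == win$ci])
}

#' Degree ranking of a core network
#'
#' @param g igraph core network.
#' @param top_k number of rows to return (all if fewer nodes).
#' @param only_flag optional name of a logical vertex attribute (e.g.
#'   `"is_deg"`) restricting the ranking to flagged nodes.
#' @return data frame `rank`, `id`, `degree`, sorted by decreasing degree,
#'   ties lexicographic on id.
#' @export
degree_ranking <- function(g, top_k = 20L, only_flag = NULL) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  deg <- igraph::degree(g)
  nm <- igraph::V(g)$name
  keep <- rep(TRUE, length(nm))
  if (!is.null(only_flag)) {
    fl <- igraph::vertex_attr(g, only_flag)
    if (is.null(fl)) stop("no vertex attribute ", only_flag)
    keep <- as.logical(fl)
  }
  df <- data.frame(id = nm[keep], degree = as.integer(deg[keep]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$id), , drop = FALSE]
  df <- utils::head(df, top_k)
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Build a core network from seeds and lncRNA target predictions
#'
#' Convenience wrapper chaining [seed_neighborhood()], [steiner_reduce()],
#' [attach_delr_targets()] and [largest_component()].
#'
#' @param g background network.
#' @param seeds seed gene ids (differentially expressed coding genes).
#' @param predictions lncRNA target table (may be empty).
#' @param delrs lncRNA ids eligible for attachment.
#' @param on_full if TRUE, run the Steiner reduction on the full background
#'   network instead of the seed neighbourhood.
#' @return igraph core network.
#' @export
build_core_network <- function(g, seeds, predictions = NULL, delrs = NULL,
                               on_full = FALSE) {
  sub <- if (on_full) g else seed_neighborhood(g, seeds)
  tree <- steiner_reduce(sub, intersect(seeds, igraph::V(sub)$name))
  if (!is.null(predictions) && nrow(predictions) > 0L)
    tree <- attach_delr_targets(tree, predictions, delrs)
  core <- largest_component(tree)
  igraph::set_vertex_attr(core, "is_deg",
                          value = igraph::V(core)$name %in% seeds)
}
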