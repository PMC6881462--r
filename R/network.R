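#' Build the background gene network from pathway files
#'
#' Parses a mixture of pathway-interaction XML files (a KGML-like dialect:
#' `entry` elements carrying one or more gene ids in their `name` attribute,
#' `relation` elements linking two entries) and/or two-column tab-separated
#' edge lists, and merges everything into one simple undirected graph.
#' Multi-id entries are expanded to all pairwise combinations of the
#' relation endpoints; direction, self-loops and duplicate edges are
#' discarded.
#'
#' @param files character vector of `.xml` and/or `.tsv`/`.txt` paths.
#' @return an `igraph` undirected graph with named vertices.
#' @export
build_background <- function(files) {
  edges <- list()
  for (f in files) {
    if (grepl("\\.xml$", f, ignore.case = TRUE))
      edges[[f]] <- parse_kgml_subset(f)
    else
      edges[[f]] <- as.matrix(utils::read.table(
        f, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
        colClasses = "character", comment.char = "#")[, 1:2])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0L) stop("no edges found in input files")
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

parse_kgml_subset <- function(path) {
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- lapply(entries, function(e)
    strsplit(xml2::xml_attr(e, "name"), "\\s+")[[1L]])
  names(ids) <- xml2::xml_attr(entries, "id")
  rels <- xml2::xml_find_all(doc, ".//relation")
  out <- lapply(rels, function(r) {
    a <- ids[[xml2::xml_attr(r, "entry1")]]
    b <- ids[[xml2::xml_attr(r, "entry2")]]
    if (is.null(a) || is.null(b)) return(NULL)
    as.matrix(expand.grid(a, b, stringsAsFactors = FALSE))
  })
  el <- do.call(rbind, out)
  if (is.null(el)) matrix(character(), ncol = 2L) else unname(el)
}

#' Flag nodes of a gene network
#'
#' Attaches logical vertex attributes (`is_deg`, `is_delr_target`,
#' `is_nei`, `is_seed`) marking gene-set membership; ids absent from the
#' graph are ignored.
#'
#' @param g igraph graph with named vertices.
#' @param deg,delr_target,nei,seed character vectors of gene ids.
#' @export
set_node_flags <- function(g, deg = NULL, delr_target = NULL, nei = NULL,
                           seed = NULL) {
  nm <- igraph::V(g)$name
  flag <- function(ids) nm %in% ids
  if (!is.null(deg)) g <- igraph::set_vertex_attr(g, "is_deg", value = flag(deg))
  if (!is.null(delr_target))
    g <- igraph::set_vertex_attr(g, "is_delr_target", value = flag(delr_target))
  if (!is.null(nei)) g <- igraph::set_vertex_attr(g, "is_nei", value = flag(nei))
  if (!is.null(seed)) g <- igraph::set_vertex_attr(g, "is_seed", value = flag(seed))
  g
}

#' Pairwise shortest-path distances between two gene sets
#'
#' BFS hop distances for every ordered pair `(a, b)` with `a` in `A`, `b`
#' in `B`, `a != b`. Unreachable pairs are kept as `Inf` in the multiset,
#' excluded from the mean, and counted against connectivity. Ids missing
#' from the graph are dropped with a message.
#'
#' @param g igraph graph with named vertices.
#' @param a,b character vectors of gene ids.
#' @return list with `distances` (numeric, possibly `Inf`), `mean_distance`
#'   (over connected pairs; `NA` when none), `connectivity` (fraction of
#'   pairs with a path), `n_pairs`.
#' @export
pairwise_distances <- function(g, a, b) {
  nm <- igraph::V(g)$name
  a0 <- unique(a); b0 <- unique(b)
  a <- intersect(a0, nm); b <- intersect(b0, nm)
  nd <- (length(a0) - length(a)) + (length(b0) - length(b))
  if (nd > 0) message(nd, " id(s) not in the network were dropped")
  if (length(a) == 0L || length(b) == 0L)
    stop("both sets empty after intersecting with the network")
  d <- igraph::distances(g, v = a, to = b)
  keep <- outer(a, b, "!=")
  vals <- as.numeric(d[keep])
  if (length(vals) == 0L) stop("no valid pairs (sets identical singletons?)")
  fin <- vals[is.finite(vals)]
  list(distances = vals,
       mean_distance = if (length(fin)) mean(fin) else NA_real_,
       connectivity = length(fin) / length(vals),
       n_pairs = length(vals))
}

#' Proximity contrast of a reference set against two gene sets
#'
#' Compares the shortest-path proximity of a reference set `r` (e.g. a
#' physiological gene set) to a set `x` (e.g. differentially expressed
#' transcripts) versus its complement `xbar`, reporting the two distance
#' multisets, their means and connectivities, and a two-sample
#' Kolmogorov-Smirnov test on the finite distances. Hop distances are
#' heavily tied, so the asymptotic KS p-value is an approximation.
#'
#' @param g igraph graph with named vertices.
#' @param r,x,xbar character vectors of gene ids; `x` and `xbar` must be
#'   disjoint.
#' @return list with `x`, `xbar` (each a [pairwise_distances()] result),
#'   `ks_stat`, `ks_p`.
#' @export
proximity_contrast <- function(g, r, x, xbar) {
  if (length(intersect(x, xbar))) stop("x and xbar must be disjoint")
  px <- pairwise_distances(g, r, x)
  pb <- pairwise_distances(g, r, xbar)
  fx <- px$distances[is.finite(px$distances)]
  fb <- pb$distances[is.finite(pb$distances)]
  if (length(fx) == 0L || length(fb) == 0L)
    stop("a distance multiset is empty; cannot compare")
  ks <- suppressWarnings(stats::ks.test(fx, fb, exact = FALSE))
  list(x = px, xbar = pb,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Write a network as GraphML and/or edge-list TSV
#'
#' @param g igraph graph.
#' @param path output path; format from extension (`.graphml` or `.tsv`).
#' @export
write_network <- function(g, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
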