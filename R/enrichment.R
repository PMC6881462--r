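#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for a hypergeometric draw of `n` genes from a background of
#' `N` of which `K` belong to the pathway: the over-representation p-value
#' of observing `k` or more pathway genes in the query.
#'
#' @param k overlap; `K` pathway size; `n` query size; `N` background size.
#' @param K,n,N see above.
#' @return p in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= 1)
  if (k > K || k > n || K > N || n > N)
    stop("inconsistent hypergeometric arguments")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read / write GMT gene-set files
#'
#' @param path GMT file: tab-separated `name`, `description`, genes...
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1L),
    USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional per-set description column.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric pathway enrichment of a gene list
#'
#' Query genes outside the background are dropped (their count is reported
#' in `attr(, "dropped")`). One row is produced per pathway with at least
#' one gene in the background.
#'
#' @param query character vector of gene ids.
#' @param gene_sets named list of pathways (character vectors), e.g. from
#'   [read_gmt()].
#' @param background character vector, the gene universe.
#' @param p_threshold `enriched` flag cutoff on the raw p.
#' @return data frame `pathway`, `N`, `K`, `n`, `k`, `p`, `bh_fdr`,
#'   `enriched`, sorted by ascending p.
#' @export
enrich <- function(query, gene_sets, background, p_threshold = 0.05) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background")
  q0 <- unique(query)
  query <- intersect(q0, background)
  dropped <- length(q0) - length(query)
  if (dropped > 0)
    message(dropped, " query gene(s) outside the background were dropped")
  rows <- lapply(names(gene_sets), function(pw) {
    set <- intersect(unique(gene_sets[[pw]]), background)
    if (length(set) == 0L) return(NULL)
    k <- length(intersect(query, set))
    data.frame(pathway = pw, N = length(background), K = length(set),
               n = length(query), k = k,
               p = hypergeom_upper_tail(k, length(set), length(query),
                                        length(background)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway overlaps the background")
  res$bh_fdr <- stats::p.adjust(res$p, method = "BH")
  res$enriched <- res$p < p_threshold
  res <- res[order(res$p, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Pathways enriched in two or more query classes
#'
#' @param ... two or more [enrich()] result tables (or a single list of
#'   them), e.g. for coding DEGs, ASGs and lncRNA targets.
#' @return character vector of pathway names whose `enriched` flag is TRUE
#'   in at least two of the tables.
#' @export
common_pathways <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !is.data.frame(tabs[[1L]])) tabs <- tabs[[1L]]
  if (length(tabs) < 2L) stop("need >= 2 enrichment tables")
  hits <- unlist(lapply(tabs, function(t) unique(t$pathway[t$enriched])))
  sort(unique(hits[duplicated(hits)]))
}
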