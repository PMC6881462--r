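#' Two-group expression matrix
#'
#' Bundles a feature-by-sample matrix of positive linear-scale intensities
#' with a case/control group label per sample. This is the base input of the
#' differential-expression and splicing stages.
#'
#' @param intensity numeric matrix, features in rows (unique rownames),
#'   samples in columns; all values must be strictly positive.
#' @param groups character or factor of length `ncol(intensity)` with exactly
#'   two levels; the level named `"case"` (if present) is treated as the case
#'   group, otherwise the first level is.
#' @param case the label identifying the case group.
#' @return An object of class `expr_matrix`: a list with elements
#'   `intensity`, `groups` (factor) and `case`.
#' @export
expression_matrix <- function(intensity, groups, case = "case") {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("intensity must have unique rownames (feature ids)")
  if (!all(is.finite(intensity)) || any(intensity <= 0))
    stop("all intensities must be positive and finite (linear scale)")
  groups <- as.factor(as.character(groups))
  if (length(groups) != ncol(intensity))
    stop("one group label per sample required")
  if (nlevels(groups) != 2L)
    stop("exactly two groups required")
  if (!case %in% levels(groups)) case <- levels(groups)[1L]
  if (min(table(groups)) < 2L)
    stop("each group needs at least 2 samples")
  structure(list(intensity = intensity, groups = groups, case = case),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s=%d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

case_cols <- function(x) x$groups == x$case
ctrl_cols <- function(x) x$groups != x$case

#' Exon-level expression matrix
#'
#' Like [expression_matrix()] but for exon probes: each row (exon) carries a
#' parent gene id and its index within the gene.
#'
#' @inheritParams expression_matrix
#' @param gene_id character, parent gene of each exon row.
#' @param exon_index integer, 1-based position of the exon within its gene.
#' @return An object of class `exon_matrix`.
#' @export
exon_matrix <- function(intensity, gene_id, exon_index, groups, case = "case") {
  em <- expression_matrix(intensity, groups, case)
  if (length(gene_id) != nrow(em$intensity) ||
      length(exon_index) != nrow(em$intensity))
    stop("gene_id and exon_index must have one entry per exon row")
  em$gene_id <- as.character(gene_id)
  em$exon_index <- as.integer(exon_index)
  class(em) <- c("exon_matrix", "expr_matrix")
  em
}

#' Write / read a two-group expression matrix as TSV
#'
#' On disk the table has features in rows and samples in columns, preceded by
#' a `#group` comment line giving the group label of each sample column.
#'
#' @param x an `expr_matrix` (or `exon_matrix`; its `gene_id`/`exon_index`
#'   become leading columns).
#' @param path file path.
#' @export
write_expression_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#group\t", paste(as.character(x$groups), collapse = "\t")),
             con)
  df <- data.frame(feature = rownames(x$intensity), check.names = FALSE)
  if (inherits(x, "exon_matrix")) {
    df$gene_id <- x$gene_id
    df$exon_index <- x$exon_index
  }
  df <- cbind(df, as.data.frame(x$intensity, check.names = FALSE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param exon logical; read as an `exon_matrix`?
#' @param case passed to the constructor.
#' @export
read_expression_tsv <- function(path, exon = FALSE, case = "case") {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#group"))
    stop("expression TSV must start with a '#group' line")
  groups <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- if (exon) c("feature", "gene_id", "exon_index") else "feature"
  mat <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(mat) <- df$feature
  if (exon)
    exon_matrix(mat, df$gene_id, df$exon_index, groups, case)
  else
    expression_matrix(mat, groups, case)
}
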