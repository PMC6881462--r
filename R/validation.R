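#' qPCR relative quantity (2^-dCT)
#'
#' `RQ = 2^-(CT_gene - CT_reference)`. With several reference genes pass
#' the arithmetic mean of their CTs (equivalent to normalising to their
#' geometric-mean abundance).
#'
#' @param ct_gene,ct_reference threshold cycles (finite).
#' @return relative quantity.
#' @export
relative_quantity <- function(ct_gene, ct_reference) {
  if (!all(is.finite(ct_gene)) || !all(is.finite(ct_reference)))
    stop("CT values must be finite")
  2^-(ct_gene - ct_reference)
}

#' Two-sample comparison of relative quantities
#'
#' Classical equal-variance two-sided Student t-test (Welch optional).
#' Zero pooled variance follows the package convention: p = 0 when the
#' means differ, 1 when they are equal.
#'
#' @param values numeric (e.g. RQ values).
#' @param groups two-level group label per value, >= 2 per group.
#' @param var_equal use the pooled-variance test (default) or Welch.
#' @return p-value.
#' @export
group_compare <- function(values, groups, var_equal = TRUE) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L || min(table(groups)) < 2L)
    stop("two groups with >= 2 values each required")
  v <- split(values, groups)
  if (stats::var(v[[1L]]) == 0 && stats::var(v[[2L]]) == 0)
    return(if (isTRUE(all.equal(mean(v[[1L]]), mean(v[[2L]])))) 1 else 0)
  stats::t.test(v[[1L]], v[[2L]], var.equal = var_equal)$p.value
}

#' ROC area under the curve by the rank statistic
#'
#' Mann-Whitney formulation: `AUC = (R1 - n1 (n1 + 1) / 2) / (n1 n0)` with
#' `R1` the rank sum of the positive class (midranks for ties), identical
#' to trapezoidal integration of the ROC curve.
#'
#' @param values numeric scores.
#' @param labels binary class per value (logical, or a two-level factor
#'   whose *second* sorted level is the positive class).
#' @param orient if TRUE, report `max(AUC, 1 - AUC)` and attach a
#'   `direction` attribute (`">"` when higher values mark the positive
#'   class, `"<"` otherwise).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(values, labels, orient = FALSE) {
  if (is.logical(labels)) pos <- labels
  else {
    lev <- sort(unique(as.character(labels)))
    if (length(lev) != 2L) stop("labels must have exactly two classes")
    pos <- as.character(labels) == lev[2L]
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values)     # midranks for ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) {
    dir <- if (auc >= 0.5) ">" else "<"
    auc <- max(auc, 1 - auc)
    attr(auc, "direction") <- dir
  }
  auc
}

#' qPCR validation of candidate genes
#'
#' Computes 2^-dCT relative quantities per sample, a per-gene Student
#' t-test between groups, and the ROC AUC for discriminating the groups.
#'
#' @param qpcr data frame with columns `sample`, `group`, `gene`, `ct`,
#'   `reference_ct` (e.g. from [read_qpcr_csv()]).
#' @param case label of the case group.
#' @return list with `samples` (per-sample RQ table) and `genes` (per-gene
#'   `gene`, `mean_rq_case`, `mean_rq_control`, `p`, `auc`, `direction`).
#' @export
validate_qpcr <- function(qpcr, case = "case") {
  need <- c("sample", "group", "gene", "ct", "reference_ct")
  if (!all(need %in% names(qpcr)))
    stop("qpcr table needs columns: ", paste(need, collapse = ", "))
  qpcr$rq <- relative_quantity(qpcr$ct, qpcr$reference_ct)
  rows <- lapply(split(qpcr, qpcr$gene), function(gq) {
    is_case <- gq$group == case
    auc <- roc_auc(gq$rq, is_case, orient = TRUE)
    data.frame(gene = gq$gene[1L],
               mean_rq_case = mean(gq$rq[is_case]),
               mean_rq_control = mean(gq$rq[!is_case]),
               p = group_compare(gq$rq, gq$group),
               auc = as.numeric(auc),
               direction = attr(auc, "direction"),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  rownames(genes) <- NULL
  list(samples = qpcr, genes = genes[order(genes$gene), , drop = FALSE])
}

#' Read / write qPCR CT tables
#'
#' CSV with columns `sample`, `group`, `gene`, `ct`, `reference_ct`.
#'
#' @param path file path.
#' @export
read_qpcr_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_qpcr_csv
#' @param qpcr the table to write.
#' @export
write_qpcr_csv <- function(qpcr, path) {
  utils::write.csv(qpcr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
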