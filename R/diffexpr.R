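#' Tukey biweight robust average
#'
#' One-step (optionally iterated) Tukey biweight location estimate, the
#' robust group average used throughout the package to summarise microarray
#' intensities. Starts at the median, scales residuals by the (unscaled)
#' median absolute deviation, and down-weights points by `(1 - u^2)^2`,
#' zeroing anything with `|u| >= 1`.
#'
#' @param x numeric vector, at least one finite value.
#' @param c tuning constant; `u = (x - M) / (c * MAD + epsilon)`. The default
#'   5 is the classical array-summarisation convention.
#' @param epsilon small positive stabiliser for the zero-MAD case.
#' @param iterations number of reweighting steps (1 = one-step estimator).
#' @return The biweight location estimate. When the MAD is zero the median is
#'   returned unchanged.
#' @examples
#' tukey_biweight(c(1, 1, 1, 1, 100))  # outlier fully discounted
#' @export
tukey_biweight <- function(x, c = 5, epsilon = 1e-4, iterations = 1L) {
  x <- as.numeric(x)
  if (length(x) == 0L || anyNA(x)) stop("x must be non-empty and NA-free")
  if (length(x) == 1L) return(x)
  m <- stats::median(x)
  for (i in seq_len(iterations)) {
    s <- stats::median(abs(x - m))
    if (s == 0) return(m)
    u <- (x - m) / (c * s + epsilon)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(m)
    m <- sum(w * x) / sum(w)
  }
  m
}

#' Per-group biweight means of a feature
#'
#' @param x an [expression_matrix()].
#' @param feature feature id (rowname).
#' @param ... passed to [tukey_biweight()].
#' @return Named numeric `c(case = ..., control = ...)` on linear scale.
#' @export
group_biweight <- function(x, feature, ...) {
  if (!feature %in% rownames(x$intensity)) stop("unknown feature: ", feature)
  v <- x$intensity[feature, ]
  c(case = tukey_biweight(v[case_cols(x)], ...),
    control = tukey_biweight(v[ctrl_cols(x)], ...))
}

#' Log2 fold change from group biweight means
#'
#' `logFC = log2(biweight case mean) - log2(biweight control mean)`, both
#' means taken on the linear intensity scale.
#'
#' @inheritParams group_biweight
#' @export
log_fold_change <- function(x, feature, ...) {
  bw <- group_biweight(x, feature, ...)
  if (any(bw <= 0)) stop("nonpositive biweight mean for ", feature)
  unname(log2(bw["case"]) - log2(bw["control"]))
}

#' One-way ANOVA p-value for a two-group comparison
#'
#' F-test p-value from the classical one-way between-subject ANOVA
#' decomposition. Degenerate inputs follow a documented convention: zero
#' within-group variance yields p = 0 when the group means differ and p = 1
#' when they are equal (an infinitely precise measurement settles the
#' question either way).
#'
#' @param values numeric vector of responses.
#' @param groups group label per value (two groups, each with >= 2 values).
#' @return The p-value.
#' @export
anova_p <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L || min(table(groups)) < 2L)
    stop("two groups with >= 2 values each required")
  means <- tapply(values, groups, mean)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw == 0)
    return(if (isTRUE(all.equal(means[[1L]], means[[2L]]))) 1 else 0)
  stats::oneway.test(values ~ groups, var.equal = TRUE)$p.value
}

#' Call differentially expressed transcripts
#'
#' Computes per-feature biweight group means (linear scale), the log2 fold
#' change of their ratio, a one-way ANOVA p-value on log2 intensities, and
#' flags features with `|logFC| >= fc_threshold` and `p < p_threshold` as
#' differentially expressed. Features are partitioned into coding (DEG) and
#' lncRNA (DELR) classes by the annotation biotype.
#'
#' @param x an [expression_matrix()].
#' @param annotation a feature annotation data frame (see
#'   [feature_annotation()]); only its `id` and `biotype` columns are used.
#'   Features absent from the annotation are excluded with a warning.
#' @param fc_threshold fold-change cutoff. With `fc_scale = "log2"`
#'   (default) it applies to `|logFC|`; with `"linear"` to the signed linear
#'   fold change `|signedFC|`.
#' @param p_threshold raw ANOVA p-value cutoff.
#' @param fc_scale interpretation of `fc_threshold`, see above.
#' @return A data frame with columns `id`, `biotype`, `bw_case`, `bw_ctrl`,
#'   `logFC`, `signedFC` (`2^logFC` when `logFC >= 0`, else `-2^(-logFC)`),
#'   `p`, `fdr` (Benjamini-Hochberg, informational only), `is_de`; sorted by
#'   `p` then decreasing `|logFC|`. Excluded feature ids are stored in
#'   `attr(, "excluded")`.
#' @export
call_de <- function(x, annotation, fc_threshold = 1.5, p_threshold = 0.05,
                    fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  ids <- rownames(x$intensity)
  known <- ids %in% annotation$id
  if (any(!known))
    warning(sum(!known), " feature(s) missing from annotation were excluded: ",
            paste(utils::head(ids[!known], 5L), collapse = ", "),
            if (sum(!known) > 5L) ", ...")
  ids <- ids[known]
  cc <- case_cols(x); kk <- ctrl_cols(x)
  logi <- log2(x$intensity)
  res <- lapply(ids, function(id) {
    v <- x$intensity[id, ]
    bw_case <- tukey_biweight(v[cc])
    bw_ctrl <- tukey_biweight(v[kk])
    lfc <- log2(bw_case) - log2(bw_ctrl)
    p <- anova_p(logi[id, ], x$groups)
    data.frame(id = id, bw_case = bw_case, bw_ctrl = bw_ctrl,
               logFC = lfc,
               signedFC = if (lfc >= 0) 2^lfc else -2^(-lfc),
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$biotype <- annotation$biotype[match(res$id, annotation$id)]
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  fc_stat <- if (fc_scale == "log2") abs(res$logFC) else abs(res$signedFC)
  res$is_de <- fc_stat >= fc_threshold & res$p < p_threshold
  res <- res[order(res$p, -abs(res$logFC), res$id), ,
             drop = FALSE]
  res <- res[, c("id", "biotype", "bw_case", "bw_ctrl", "logFC", "signedFC",
                 "p", "fdr", "is_de")]
  rownames(res) <- NULL
  attr(res, "excluded") <- setdiff(rownames(x$intensity), ids)
  res
}

#' Split a DE table into coding and lncRNA calls
#'
#' @param de result of [call_de()].
#' @return list with elements `deg` (coding ids called DE) and `delr`
#'   (lncRNA ids called DE).
#' @export
de_classes <- function(de) {
  list(deg = de$id[de$is_de & de$biotype == "coding"],
       delr = de$id[de$is_de & de$biotype == "lncRNA"])
}
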