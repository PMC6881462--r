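#' Splicing index of one exon
#'
#' Ratio of the exon's relative intensity (exon / parent gene) between the
#' case and control groups, each summarised by the Tukey biweight:
#' `SI = (bw_exon_case / bw_gene_case) / (bw_exon_ctrl / bw_gene_ctrl)`.
#' An exon that tracks its gene in both groups has SI = 1.
#'
#' @param exons an [exon_matrix()].
#' @param genes the matching gene-level [expression_matrix()].
#' @param exon exon id (rowname of `exons`).
#' @return The (strictly positive) splicing index.
#' @export
splicing_index <- function(exons, genes, exon) {
  if (!exon %in% rownames(exons$intensity)) stop("unknown exon: ", exon)
  gene <- exons$gene_id[match(exon, rownames(exons$intensity))]
  bwe <- group_biweight(exons, exon)
  bwg <- group_biweight(genes, gene)
  if (any(bwg <= 0) || any(bwe <= 0)) stop("nonpositive group summary")
  unname((bwe["case"] / bwg["case"]) / (bwe["control"] / bwg["control"]))
}

signed_ratio <- function(r) ifelse(r >= 1, r, -1 / r)

#' Call alternatively spliced genes
#'
#' Computes per-exon splicing indices (group-level biweight summaries), a
#' one-way ANOVA p-value on the per-sample log2(exon/gene) normalised
#' signal, and flags a gene as alternatively spliced (ASG) when any of its
#' exons has `|signed SI| >= si_threshold` and `p < p_threshold`. Each
#' multi-exon gene's signed-SI-by-exon profile is then matched against the
#' canonical event templates by [classify_event()].
#'
#' @inheritParams splicing_index
#' @param si_threshold cutoff on the signed SI (ratio if >= 1, else its
#'   negative reciprocal, so the scale is symmetric around +/-1).
#' @param p_threshold per-exon ANOVA p cutoff.
#' @return list with `exons`: per-exon data frame (`exon`, `gene`,
#'   `exon_index`, `si`, `signed_si`, `p`, `eees`, `label`, `passes`), and
#'   `genes`: per-gene data frame (`gene`, `n_exons`, `is_asg`, `eees`,
#'   `label`, `best_exon`). Single-exon genes are skipped with a warning.
#' @export
call_asg <- function(exons, genes, si_threshold = 2, p_threshold = 0.05) {
  ids <- rownames(exons$intensity)
  n_ex <- table(exons$gene_id)
  single <- names(n_ex)[n_ex < 2L]
  if (length(single))
    warning(length(single), " single-exon gene(s) skipped: ",
            paste(utils::head(single, 5L), collapse = ", "))
  keep <- !(exons$gene_id %in% single)
  if (!any(keep)) stop("no multi-exon genes to test")

  glog <- log2(genes$intensity)
  per_exon <- lapply(which(keep), function(i) {
    exon <- ids[i]; gene <- exons$gene_id[i]
    si <- splicing_index(exons, genes, exon)
    norm <- log2(exons$intensity[i, ]) - glog[gene, ]
    data.frame(exon = exon, gene = gene, exon_index = exons$exon_index[i],
               si = si, signed_si = signed_ratio(si),
               p = anova_p(norm, exons$groups), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_exon)
  tab <- tab[order(tab$gene, tab$exon_index), , drop = FALSE]
  tab$passes <- abs(tab$signed_si) >= si_threshold & tab$p < p_threshold

  per_gene <- lapply(split(tab, tab$gene), function(g) {
    cls <- if (nrow(g) >= 3L) classify_event(g$signed_si)
           else list(eees = NA_real_, label = "unlabeled")
    hit <- which(g$passes)
    best <- if (length(hit)) g$exon[hit[which.max(abs(g$signed_si[hit]))]]
            else g$exon[which.max(abs(g$signed_si))]
    data.frame(gene = g$gene[1L], n_exons = nrow(g), is_asg = any(g$passes),
               eees = cls$eees, label = cls$label, best_exon = best,
               stringsAsFactors = FALSE)
  })
  gtab <- do.call(rbind, per_gene)
  rownames(gtab) <- NULL
  tab$eees <- gtab$eees[match(tab$gene, gtab$gene)]
  tab$label <- gtab$label[match(tab$gene, gtab$gene)]
  rownames(tab) <- NULL
  list(exons = tab, genes = gtab[order(gtab$gene), , drop = FALSE])
}

event_templates <- function(n) {
  ## Each template is a named numeric profile over exon positions 1..n.
  tmpl <- list()
  spike <- function(i) { v <- numeric(n); v[i] <- 1; v }
  for (j in seq(2L, n - 1L))
    tmpl[[paste0("cassette exon@", j)]] <- spike(j)
  tmpl[["alt 5' donor@1"]] <- spike(1L)
  tmpl[[paste0("alt 3' acceptor@", n)]] <- spike(n)
  if (n >= 4L)
    for (j in seq(2L, n - 2L)) {              # plateau over an intron-flanked pair
      v <- numeric(n); v[c(j, j + 1L)] <- 1
      tmpl[[paste0("intron retention@", j)]] <- v
    }
  interior <- seq(2L, n - 1L)
  if (length(interior) >= 2L)
    for (i in interior) for (j in interior) if (i != j) {
      v <- numeric(n); v[i] <- 1; v[j] <- -1
      tmpl[[paste0("mutually exclusive exons@", i, ",", j)]] <- v
    }
  tmpl
}

#' Label a splice-event profile
#'
#' Scores a gene's signed-SI-by-exon profile against canonical event
#' templates (interior spike = cassette exon; spike at the first / last exon
#' = alternative 5' donor / 3' acceptor; two-exon plateau = intron
#' retention; one up- and one down-spike = mutually exclusive exons). The
#' exon event estimation score (EEES) is the maximum Pearson correlation
#' over templates; the gene is labelled with the best template's event when
#' EEES > `threshold`, else `"unlabeled"`.
#'
#' @param profile numeric signed-SI per exon, length >= 3.
#' @param threshold labelling cutoff on the EEES.
#' @return list with `eees` (in `[-1, 1]`, 0 for a constant profile) and
#'   `label`.
#' @export
classify_event <- function(profile, threshold = 0.2) {
  n <- length(profile)
  if (n < 3L) stop("profile needs >= 3 exons")
  ## correlate on the log-ratio scale: sign(s) * log2(|s|) is exactly
  ## log2(SI), continuous through SI = 1 where the signed scale jumps
  ## between +1 and -1 under noise
  profile <- sign(profile) * log2(pmax(abs(profile), 1))
  if (stats::sd(profile) == 0)
    return(list(eees = 0, label = "unlabeled"))
  tmpl <- event_templates(n)
  cors <- vapply(tmpl, function(t) stats::cor(profile, t), numeric(1L))
  best <- which.max(cors)
  eees <- unname(cors[best])
  label <- sub("@.*$", "", names(cors)[best])
  if (eees <= threshold) label <- "unlabeled"
  list(eees = eees, label = label)
}
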