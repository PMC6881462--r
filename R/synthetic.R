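#' Simulation design for a planted two-group transcriptome study
#'
#' Describes every input the pipeline consumes, with planted ground truth:
#' a two-group log-normal intensity experiment with planted fold changes,
#' exon profiles with planted splicing events, lncRNAs placed inside or far
#' outside the 10-kb cis window of genes, a modular background network with
#' a designated physiological (NEI-style) reference gene set, pathways with
#' one planted enriched set, and qPCR CT shifts. The default group sizes
#' (6 cases vs 5 controls) match a small two-arm microarray cohort.
#'
#' @param seed integer master seed; every generator derives its stream from
#'   it, so a design is a pure function of its arguments.
#' @param n_case,n_control samples per group (>= 2).
#' @param n_genes,n_lncrnas coding genes / lncRNAs in the universe. Ids are
#'   `G0001...` and `L001...`.
#' @param planted_de named numeric: signed linear fold change per feature
#'   (gene or lncRNA id); `|FC| >= 1`. Sign gives direction (`-4` = 4-fold
#'   down in cases).
#' @param planted_splice data frame `gene`, `label` (`"cassette exon"` or
#'   `"mutually exclusive exons"`), `magnitude` (SI ratio planted in the
#'   case group), optional `exon_index` (NA = middle interior exon).
#' @param planted_cis_pairs data frame `lncrna`, `gene`: pairs whose 10-kb
#'   windows are made to overlap. All other lncRNAs are placed on a
#'   gene-free chromosome.
#' @param planted_trans_pairs data frame `lncrna`, `gene`: mRNAs that get a
#'   40-nt reverse complement of the lncRNA embedded.
#' @param noise_sd log2-scale intensity noise SD.
#' @param network_modules,module_size planted-partition background network:
#'   the first `network_modules * module_size` gene ids become nodes,
#'   assigned to modules in blocks.
#' @param p_in,p_out within/between-module edge probabilities,
#'   `0 < p_out < p_in <= 1`.
#' @param hub_gene optional gene id wired to every node of its own module
#'   (a planted hub).
#' @param nei_size,nei_bias size of the designated reference ("NEI") gene
#'   set and the probability that each member is drawn from the module
#'   holding `hub_gene` (module 1 if unset) rather than uniformly from the
#'   rest.
#' @param n_pathways,pathway_size random pathway gene sets for the GMT.
#' @param planted_pathway character vector of gene ids forming the pathway
#'   intended to be enriched (written as set `pw_planted`).
#' @return validated list of class `simulation_design`.
#' @export
simulation_design <- function(seed = 1L, n_case = 6L, n_control = 5L,
                              n_genes = 200L, n_lncrnas = 20L,
                              planted_de = numeric(),
                              planted_splice = NULL,
                              planted_cis_pairs = NULL,
                              planted_trans_pairs = NULL,
                              noise_sd = 0.5,
                              network_modules = 4L, module_size = 30L,
                              p_in = 0.15, p_out = 0.01,
                              hub_gene = NULL,
                              nei_size = 15L, nei_bias = 0.8,
                              n_pathways = 20L, pathway_size = 15L,
                              planted_pathway = NULL) {
  d <- list(seed = as.integer(seed), n_case = as.integer(n_case),
            n_control = as.integer(n_control),
            n_genes = as.integer(n_genes), n_lncrnas = as.integer(n_lncrnas),
            planted_de = planted_de, planted_splice = planted_splice,
            planted_cis_pairs = planted_cis_pairs,
            planted_trans_pairs = planted_trans_pairs,
            noise_sd = noise_sd,
            network_modules = as.integer(network_modules),
            module_size = as.integer(module_size),
            p_in = p_in, p_out = p_out, hub_gene = hub_gene,
            nei_size = as.integer(nei_size), nei_bias = nei_bias,
            n_pathways = as.integer(n_pathways),
            pathway_size = as.integer(pathway_size),
            planted_pathway = planted_pathway)
  d$gene_ids <- sprintf("G%04d", seq_len(d$n_genes))
  d$lnc_ids <- sprintf("L%03d", seq_len(d$n_lncrnas))
  universe <- c(d$gene_ids, d$lnc_ids)
  if (d$n_case < 2L || d$n_control < 2L) stop("need >= 2 samples per group")
  if (length(d$planted_de)) {
    if (is.null(names(d$planted_de)) ||
        !all(names(d$planted_de) %in% universe))
      stop("planted_de names must be gene/lncRNA ids of the universe")
    if (any(abs(d$planted_de) < 1)) stop("planted |FC| must be >= 1")
  }
  if (!is.null(d$planted_splice)) {
    if (!all(d$planted_splice$gene %in% d$gene_ids))
      stop("planted_splice genes must be coding gene ids")
    if (any(d$planted_splice$magnitude <= 1))
      stop("planted SI magnitudes must be > 1")
  }
  if (!is.null(d$planted_cis_pairs)) {
    if (!all(d$planted_cis_pairs$lncrna %in% d$lnc_ids) ||
        !all(d$planted_cis_pairs$gene %in% d$gene_ids))
      stop("planted_cis_pairs must reference existing lncRNA and gene ids")
  }
  if (d$network_modules < 2L) stop("need >= 2 network modules")
  if (d$network_modules * d$module_size > d$n_genes)
    stop("network larger than the gene universe")
  if (!(d$p_in > 0 && d$p_in <= 1 && d$p_out >= 0 && d$p_out <= 1))
    stop("p_in must lie in (0, 1] and p_out in [0, 1]")
  if (d$p_in <= d$p_out) stop("p_in must exceed p_out")
  if (!is.null(d$hub_gene) && !d$hub_gene %in% d$gene_ids)
    stop("hub_gene must be a coding gene id")
  if (!is.null(d$planted_pathway) &&
      !all(d$planted_pathway %in% d$gene_ids))
    stop("planted_pathway must contain coding gene ids")
  structure(d, class = "simulation_design")
}

design_groups <- function(d) {
  factor(rep(c("case", "control"), c(d$n_case, d$n_control)),
         levels = c("case", "control"))
}

#' Generate gene- and exon-level expression with planted signals
#'
#' Per-feature linear intensities are `2^(mu + effect * case + N(0, sd))`
#' with `mu ~ U(7, 11)` and `effect = sign(FC) * log2(|FC|)` for planted
#' features (0 otherwise). Each coding gene gets 4-10 exons whose
#' intensities track the realised gene signal up to a fixed exon offset and
#' exon-level noise; planted splice exons are additionally multiplied by
#' the planted SI magnitude in the case group only (divided, for the
#' second exon of a mutually-exclusive event). With `noise_sd = 0` every
#' downstream estimate is exact.
#'
#' @param design a [simulation_design()].
#' @return list with `gene` ([expression_matrix()] over genes + lncRNAs),
#'   `exon` ([exon_matrix()] over coding genes) and `truth` (realised
#'   planted DE effects and splice events).
#' @export
generate_expression <- function(design) {
  d <- design
  set.seed(d$seed)
  groups <- design_groups(d)
  feats <- c(d$gene_ids, d$lnc_ids)
  ns <- length(groups)
  mu <- stats::runif(length(feats), 7, 11)
  names(mu) <- feats
  eff <- stats::setNames(numeric(length(feats)), feats)
  if (length(d$planted_de))
    eff[names(d$planted_de)] <-
      sign(d$planted_de) * log2(abs(d$planted_de))
  is_case <- as.numeric(groups == "case")
  logm <- outer(mu, rep(1, ns)) + outer(eff, is_case) +
    matrix(stats::rnorm(length(feats) * ns, 0, d$noise_sd),
           nrow = length(feats))
  gene_mat <- 2^logm
  colnames(gene_mat) <- c(sprintf("case_%d", seq_len(d$n_case)),
                          sprintf("ctrl_%d", seq_len(d$n_control)))
  rownames(gene_mat) <- feats

  ## exon layer (coding genes only)
  n_ex <- sample(4:10, d$n_genes, replace = TRUE)
  names(n_ex) <- d$gene_ids
  splice <- d$planted_splice
  realized <- NULL
  ex_rows <- list()
  for (g in d$gene_ids) {
    k <- n_ex[[g]]
    rel <- stats::runif(k, -1, 1)                      # fixed exon offsets, log2
    noise <- matrix(stats::rnorm(k * ns, 0, d$noise_sd), nrow = k)
    mult <- matrix(0, nrow = k, ncol = ns)             # planted effect, log2
    if (!is.null(splice) && g %in% splice$gene) {
      row <- splice[match(g, splice$gene), ]
      j <- row$exon_index
      if (is.null(j) || is.na(j)) j <- max(2L, (k + 1L) %/% 2L)
      j <- min(j, k - 1L)
      lm2 <- log2(row$magnitude)
      mult[j, is_case == 1] <- lm2
      j2 <- NA_integer_
      if (row$label == "mutually exclusive exons") {
        j2 <- if (j + 1L <= k - 1L) j + 1L else j - 1L
        mult[j2, is_case == 1] <- -lm2
      }
      realized <- rbind(realized,
                        data.frame(gene = g, exon_index = j,
                                   exon_index2 = j2, label = row$label,
                                   magnitude = row$magnitude,
                                   stringsAsFactors = FALSE))
    }
    m <- 2^(matrix(log2(gene_mat[g, ]), nrow = k, ncol = ns, byrow = TRUE) +
              rel + noise + mult)
    rownames(m) <- sprintf("%s_E%02d", g, seq_len(k))
    ex_rows[[g]] <- m
  }
  exon_mat <- do.call(rbind, ex_rows)
  colnames(exon_mat) <- colnames(gene_mat)
  exon_gene <- rep(d$gene_ids, n_ex)
  exon_idx <- unlist(lapply(n_ex, seq_len), use.names = FALSE)

  list(gene = expression_matrix(gene_mat, groups),
       exon = exon_matrix(exon_mat, exon_gene, exon_idx, groups),
       truth = list(de_effect = eff[eff != 0], splice = realized))
}

#' Generate a genomic annotation with planted cis geometry
#'
#' Coding genes are tiled along one chromosome with 100-kb spacing so
#' 10-kb windows can never collide by accident. Each planted cis pair
#' places its lncRNA 3-9 kb downstream of the partner gene (inside the
#' 10-kb window); every unplanted lncRNA goes to a gene-free chromosome,
#' hence is trivially >= 50 kb from every gene.
#'
#' @param design a [simulation_design()].
#' @return a [feature_annotation()] covering all genes and lncRNAs.
#' @export
generate_annotation <- function(design) {
  d <- design
  set.seed(d$seed + 1L)
  spacing <- 100000L
  gw <- as.integer(round(stats::runif(d$n_genes, 2000, 8000)))
  gstart <- 1L + (seq_len(d$n_genes) - 1L) * spacing
  gstrand <- sample(c("+", "-"), d$n_genes, replace = TRUE)
  genes <- feature_annotation(d$gene_ids, "chr1", gstart, gstart + gw - 1L,
                              gstrand, "coding")
  cis <- d$planted_cis_pairs
  lstart <- integer(d$n_lncrnas); lend <- integer(d$n_lncrnas)
  lchrom <- character(d$n_lncrnas)
  lw <- as.integer(round(stats::runif(d$n_lncrnas, 500, 2000)))
  seen <- c()
  u <- 0L
  for (i in seq_len(d$n_lncrnas)) {
    id <- d$lnc_ids[i]
    if (!is.null(cis) && id %in% cis$lncrna) {
      g <- cis$gene[match(id, cis$lncrna)]
      occ <- sum(seen == g)
      seen <- c(seen, g)
      gap <- 3000L + occ * 3000L                # 3, 6, 9 kb: inside the window
      ge <- genes$end[match(g, genes$id)]
      lchrom[i] <- "chr1"
      lstart[i] <- ge + gap + 1L
      lend[i] <- lstart[i] + lw[i] - 1L
    } else {
      lchrom[i] <- "chrU"
      lstart[i] <- 1L + u * spacing
      lend[i] <- lstart[i] + lw[i] - 1L
      u <- u + 1L
    }
  }
  lstrand <- sample(c("+", "-"), d$n_lncrnas, replace = TRUE)
  lncs <- feature_annotation(d$lnc_ids, lchrom, lstart, lend, lstrand,
                             "lncRNA")
  out <- rbind(genes, lncs)
  class(out) <- c("feature_annotation", "data.frame")
  out
}

#' Generate a modular background network with a designated reference set
#'
#' Planted-partition random graph over the first
#' `network_modules * module_size` gene ids (block module assignment):
#' within-module edges with probability `p_in`, between-module with
#' `p_out`. The optional `hub_gene` is wired to every node of its module.
#' Unless `connect = FALSE`, components are patched together by edges
#' between their lexicographically smallest nodes so the result is
#' connected. The reference ("NEI") set draws each member from the hub's
#' module with probability `nei_bias`, else uniformly from the others, so
#' proximity contrasts toward the planted module are recoverable.
#'
#' @param design a [simulation_design()].
#' @param connect patch the graph to be connected (default TRUE).
#' @return list with `graph` (igraph), `membership` (named planted module
#'   id per node) and `nei` (character vector).
#' @export
generate_network <- function(design, connect = TRUE) {
  d <- design
  set.seed(d$seed + 2L)
  nodes <- d$gene_ids[seq_len(d$network_modules * d$module_size)]
  memb <- rep(seq_len(d$network_modules), each = d$module_size)
  names(memb) <- nodes
  n <- length(nodes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(memb[pairs[, 1L]] == memb[pairs[, 2L]], d$p_in, d$p_out)
  keep <- stats::runif(nrow(pairs)) < p
  el <- cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]])
  if (!is.null(d$hub_gene)) {
    hm <- memb[[d$hub_gene]]
    others <- setdiff(nodes[memb == hm], d$hub_gene)
    el <- rbind(el, cbind(d$hub_gene, others))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  iso <- setdiff(nodes, igraph::V(g)$name)
  if (length(iso)) g <- igraph::add_vertices(g, length(iso), name = iso)
  g <- igraph::simplify(g)
  if (connect) {
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      nm <- igraph::V(g)$name
      anchors <- sort(vapply(seq_len(comp$no),
                             function(ci) min(nm[comp$membership == ci]),
                             character(1L)))
      for (i in seq_len(length(anchors) - 1L))
        g <- igraph::add_edges(g, c(anchors[i], anchors[i + 1L]))
    }
  }
  ## reference gene set, biased toward the hub's module
  target_mod <- if (!is.null(d$hub_gene)) memb[[d$hub_gene]] else 1L
  in_mod <- nodes[memb == target_mod]
  out_mod <- setdiff(nodes, in_mod)
  take_in <- stats::runif(d$nei_size) < d$nei_bias
  n_in <- min(sum(take_in), length(in_mod))
  nei <- c(sample(in_mod, n_in),
           sample(out_mod, d$nei_size - n_in))
  list(graph = g, membership = memb, nei = sort(nei))
}

#' Generate pathway gene sets with one planted enriched set
#'
#' `n_pathways` random sets of `pathway_size` coding genes, plus (when the
#' design plants one) the set `pw_planted`.
#'
#' @param design a [simulation_design()].
#' @return named list of character vectors.
#' @export
generate_pathways <- function(design) {
  d <- design
  set.seed(d$seed + 3L)
  sets <- lapply(seq_len(d$n_pathways), function(i)
    sort(sample(d$gene_ids, d$pathway_size)))
  names(sets) <- sprintf("pw_%02d", seq_len(d$n_pathways))
  if (!is.null(d$planted_pathway))
    sets$pw_planted <- sort(unique(d$planted_pathway))
  sets
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Generate lncRNA and mRNA sequences for the trans screen
#'
#' Random i.i.d. nucleotide sequences; for each planted trans pair a 40-nt
#' reverse complement of the lncRNA's 5' end is embedded in the middle of
#' the partner mRNA.
#'
#' @param design a [simulation_design()].
#' @param n_mrna how many coding genes get an mRNA (first ids taken).
#' @param lnc_len,mrna_len sequence lengths in nt.
#' @return list of named character vectors `lnc` and `mrna`.
#' @export
generate_sequences <- function(design, n_mrna = 20L, lnc_len = 500L,
                               mrna_len = 1000L) {
  d <- design
  set.seed(d$seed + 4L)
  lnc <- stats::setNames(vapply(d$lnc_ids, function(i) random_seq(lnc_len),
                                character(1L)), d$lnc_ids)
  mids <- d$gene_ids[seq_len(min(n_mrna, d$n_genes))]
  mrna <- stats::setNames(vapply(mids, function(i) random_seq(mrna_len),
                                 character(1L)), mids)
  tp <- d$planted_trans_pairs
  if (!is.null(tp)) for (i in seq_len(nrow(tp))) {
    l <- tp$lncrna[i]; g <- tp$gene[i]
    if (!g %in% names(mrna)) next
    frag <- substr(lnc[[l]], 1L, 40L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(frag)))
    s <- mrna[[g]]
    at <- nchar(s) %/% 2L
    mrna[[g]] <- paste0(substr(s, 1L, at), rc,
                        substr(s, at + 41L, nchar(s)))
  }
  list(lnc = lnc, mrna = mrna)
}

#' Generate a qPCR CT table with planted group shifts
#'
#' CT values are drawn normally around per-group means; each sample also
#' receives a reference-gene (housekeeping) CT.
#'
#' @param group_means data frame `gene`, `case`, `control` (mean CT per
#'   group; all in (0, 45)).
#' @param sd CT noise standard deviation (cycles).
#' @param n_case,n_control samples per group.
#' @param seed integer seed.
#' @param ref_ct mean reference-gene CT.
#' @return data frame `sample`, `group`, `gene`, `ct`, `reference_ct`.
#' @export
generate_qpcr <- function(group_means, sd = 0.5, n_case = 5L,
                          n_control = 17L, seed = 1L, ref_ct = 18) {
  if (!all(unlist(group_means[, c("case", "control")]) > 0 &
           unlist(group_means[, c("case", "control")]) < 45))
    stop("CT means must lie in (0, 45)")
  set.seed(as.integer(seed))
  samples <- c(sprintf("case_%d", seq_len(n_case)),
               sprintf("ctrl_%d", seq_len(n_control)))
  grp <- rep(c("case", "control"), c(n_case, n_control))
  ref <- stats::rnorm(length(samples), ref_ct, sd)
  rows <- lapply(seq_len(nrow(group_means)), function(i) {
    mu <- ifelse(grp == "case", group_means$case[i], group_means$control[i])
    data.frame(sample = samples, group = grp, gene = group_means$gene[i],
               ct = stats::rnorm(length(samples), mu, sd),
               reference_ct = ref, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
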