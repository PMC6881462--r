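stage_fail <- function(stage, e) {
  stop(structure(class = c("lncore_stage_error", "error", "condition"),
                 list(message = sprintf("stage %s: %s", stage,
                                        conditionMessage(e)),
                      call = NULL, stage = stage)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_fail(stage, e))
}

prov_write <- function(df, path, provenance) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# provenance: ", provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

input_hash <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1L))]
  paths <- unlist(paths)
  paths <- paths[file.exists(paths)]
  unname(tools::md5sum(paths))
}

#' Run the whole transcriptome pipeline from one configuration
#'
#' Executes differential expression, splicing (skipped with a notice when
#' no exon matrix is configured), lncRNA target prediction, pathway
#' enrichment of the DEG / ASG / lncRNA-target classes, background-network
#' construction, proximity contrast of the reference gene set against
#' differential vs non-differential network genes, core-network extraction
#' (seed neighbourhood, Steiner reduction, lncRNA attachment, largest
#' component), simulated-annealing module decomposition, and qPCR
#' validation. Every output table carries a provenance header with the MD5
#' hashes of the inputs; given fixed seeds the run is byte-identical.
#'
#' @param config named list (or path to a YAML file) with elements:
#'   `expression` (gene-level TSV), optional `exons` (exon TSV),
#'   `annotation` (GTF), `pathways` (GMT), `network` (edge-list TSV and/or
#'   KGML-like XML; may be a vector), `nei` (one gene id per line),
#'   optional `lnc_fasta`/`mrna_fasta`, optional `qpcr` (CSV), `outdir`,
#'   and optional `thresholds` (named list overriding `fc`, `p`, `si`,
#'   `eees`, `cis_window`, `trans_score`, `enrich_p`) and `anneal_seed`.
#' @return invisible list with the in-memory results of every stage plus
#'   `manifest`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  thr <- utils::modifyList(
    list(fc = 1.5, p = 0.05, si = 2, eees = 0.2, cis_window = 10000,
         trans_score = 30, enrich_p = 0.05),
    config$thresholds %||% list())
  outdir <- config$outdir %||% stop("config$outdir required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- paste(input_hash(config[c("expression", "exons", "annotation",
                                    "pathways", "network", "nei",
                                    "lnc_fasta", "mrna_fasta", "qpcr")]),
                collapse = ",")
  res <- list()

  ## -- differential expression ------------------------------------------
  anno <- run_stage("annotation", read_annotation(config$annotation))
  expr <- run_stage("de", read_expression_tsv(config$expression))
  de <- run_stage("de", call_de(expr, anno, fc_threshold = thr$fc,
                                p_threshold = thr$p))
  classes <- de_classes(de)
  prov_write(de, file.path(outdir, "de.tsv"), prov)
  res$de <- de

  ## -- alternative splicing ---------------------------------------------
  asg_genes <- character()
  if (!is.null(config$exons)) {
    exons <- run_stage("splice", read_expression_tsv(config$exons,
                                                     exon = TRUE))
    spl <- run_stage("splice",
                     suppressWarnings(call_asg(exons, expr,
                                               si_threshold = thr$si,
                                               p_threshold = thr$p)))
    prov_write(spl$exons, file.path(outdir, "splice.tsv"), prov)
    prov_write(spl$genes, file.path(outdir, "splice_genes.tsv"), prov)
    asg_genes <- spl$genes$gene[spl$genes$is_asg]
    res$splice <- spl
  } else message("no exon matrix configured; splicing stage skipped")

  ## -- lncRNA targets ----------------------------------------------------
  targets <- run_stage("targets",
                       predict_cis(anno, lncrnas = classes$delr,
                                   window = thr$cis_window))
  if (!is.null(config$lnc_fasta) && !is.null(config$mrna_fasta)) {
    lseq <- Biostrings::readDNAStringSet(config$lnc_fasta)
    mseq <- Biostrings::readDNAStringSet(config$mrna_fasta)
    lseq <- lseq[intersect(names(lseq), classes$delr)]
    tr <- run_stage("targets",
                    predict_trans(lseq, mseq,
                                  score_threshold = thr$trans_score))
    targets <- rbind(targets, tr)
  }
  prov_write(targets, file.path(outdir, "targets.tsv"), prov)
  res$targets <- targets

  ## -- pathway enrichment -------------------------------------------------
  gmt <- run_stage("enrich", read_gmt(config$pathways))
  background <- anno$id[anno$biotype == "coding"]
  queries <- list(deg = classes$deg, asg = asg_genes,
                  delr_target = unique(targets$gene))
  enr <- list()
  for (cls in names(queries)) {
    if (length(queries[[cls]]) == 0L) next
    enr[[cls]] <- run_stage("enrich",
                            suppressMessages(
                              enrich(queries[[cls]], gmt, background,
                                     p_threshold = thr$enrich_p)))
  }
  enr_tab <- do.call(rbind, lapply(names(enr), function(cls)
    cbind(class = cls, enr[[cls]])))
  prov_write(enr_tab, file.path(outdir, "enrichment.tsv"), prov)
  res$enrichment <- enr
  res$common_pathways <- if (length(enr) >= 2L) common_pathways(enr)
                         else character()

  ## -- background network and proximity ------------------------------------
  g <- run_stage("net", build_background(unlist(config$network)))
  nei <- run_stage("net", readLines(config$nei))
  dets <- c(classes$deg, classes$delr)
  g <- set_node_flags(g, deg = classes$deg, nei = nei, seed = classes$deg,
                      delr_target = unique(targets$gene))
  write_network(g, file.path(outdir, "background.graphml"))
  write_network(g, file.path(outdir, "background_edges.tsv"))
  nm <- igraph::V(g)$name
  x <- intersect(dets, nm)
  xbar <- setdiff(nm, c(x, nei))
  prx <- run_stage("proximity",
                   suppressMessages(proximity_contrast(g, nei, x, xbar)))
  jsonlite::write_json(
    list(provenance = prov,
         det = list(mean_distance = prx$x$mean_distance,
                    connectivity = prx$x$connectivity,
                    n_pairs = prx$x$n_pairs),
         non_det = list(mean_distance = prx$xbar$mean_distance,
                        connectivity = prx$xbar$connectivity,
                        n_pairs = prx$xbar$n_pairs),
         ks_stat = prx$ks_stat, ks_p = prx$ks_p),
    file.path(outdir, "proximity.json"), auto_unbox = TRUE, digits = NA)
  res$proximity <- prx

  ## -- core network ---------------------------------------------------------
  core <- run_stage("corenet",
                    suppressWarnings(
                      build_core_network(g, seeds = intersect(classes$deg, nm),
                                         predictions = targets,
                                         delrs = classes$delr)))
  write_network(core, file.path(outdir, "core.graphml"))
  write_network(core, file.path(outdir, "core_edges.tsv"))
  degtab <- degree_ranking(core, top_k = 20L)
  prov_write(degtab, file.path(outdir, "degrees.tsv"), prov)
  res$core <- core
  res$degree_ranking <- degtab

  ## -- module decomposition --------------------------------------------------
  part <- run_stage("modules",
                    anneal_partition(core,
                                     seed = config$anneal_seed %||% 1L))
  labels <- run_stage("modules",
                      module_function_labels(part$membership, gmt,
                                             background = background))
  mod_tab <- data.frame(id = names(part$membership),
                        module = unname(part$membership),
                        stringsAsFactors = FALSE)
  mod_tab <- mod_tab[order(mod_tab$id), , drop = FALSE]
  prov_write(mod_tab, file.path(outdir, "modules.tsv"), prov)
  prov_write(labels, file.path(outdir, "module_labels.tsv"), prov)
  res$partition <- part
  res$module_labels <- labels

  ## -- qPCR validation --------------------------------------------------------
  if (!is.null(config$qpcr)) {
    q <- run_stage("qpcr", validate_qpcr(read_qpcr_csv(config$qpcr)))
    prov_write(q$genes, file.path(outdir, "qpcr.tsv"), prov)
    res$qpcr <- q
  }

  manifest <- list(package = "lncore",
                   version = as.character(utils::packageVersion("lncore")),
                   thresholds = thr,
                   anneal_seed = config$anneal_seed %||% 1L,
                   inputs = as.list(input_hash(
                     config[c("expression", "exons", "annotation", "pathways",
                              "network", "nei", "lnc_fasta", "mrna_fasta",
                              "qpcr")])))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a complete synthetic dataset and its pipeline configuration
#'
#' Materialises every input [run_all()] consumes from one
#' [simulation_design()]: expression and exon TSVs, GTF annotation,
#' pathway GMT, network edge list, reference gene-set file, FASTA
#' sequences, a qPCR CSV, and a YAML configuration pointing at them all.
#'
#' @param design a [simulation_design()].
#' @param dir output directory (created).
#' @param qpcr_shift data frame `gene`, `case`, `control` of CT means for
#'   the qPCR table (NULL for a small default derived from the design's
#'   planted DE genes).
#' @return the configuration as a named list (also written to
#'   `config.yaml`); the planted truth is attached as `attr(, "truth")`.
#' @export
write_dataset <- function(design, dir, qpcr_shift = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  sim <- generate_expression(design)
  write_expression_tsv(sim$gene, p("expression.tsv"))
  write_expression_tsv(sim$exon, p("exons.tsv"))
  anno <- generate_annotation(design)
  write_annotation(anno, p("annotation.gtf"))
  sets <- generate_pathways(design)
  write_gmt(sets, p("pathways.gmt"))
  net <- generate_network(design)
  write_network(net$graph, p("network_edges.tsv"))
  writeLines(net$nei, p("nei.txt"))
  seqs <- generate_sequences(design)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs$lnc),
                              p("lnc.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs$mrna),
                              p("mrna.fasta"))
  if (is.null(qpcr_shift)) {
    cand <- utils::head(names(design$planted_de), 3L)
    shift <- if (length(cand))
      sign(design$planted_de[cand]) * log2(abs(design$planted_de[cand]))
    else 0
    if (length(cand) == 0L) cand <- design$gene_ids[1L]
    ## higher expression in cases = fewer amplification cycles
    qpcr_shift <- data.frame(gene = cand, case = 24 - shift, control = 24,
                             stringsAsFactors = FALSE)
  }
  qp <- generate_qpcr(qpcr_shift, sd = 0.5, seed = design$seed + 5L)
  write_qpcr_csv(qp, p("qpcr.csv"))
  config <- list(expression = p("expression.tsv"),
                 exons = p("exons.tsv"),
                 annotation = p("annotation.gtf"),
                 pathways = p("pathways.gmt"),
                 network = p("network_edges.tsv"),
                 nei = p("nei.txt"),
                 lnc_fasta = p("lnc.fasta"),
                 mrna_fasta = p("mrna.fasta"),
                 qpcr = p("qpcr.csv"),
                 outdir = p("results"),
                 anneal_seed = design$seed)
  yaml::write_yaml(config, p("config.yaml"))
  attr(config, "truth") <- list(design = design,
                                de = names(design$planted_de),
                                splice = sim$truth$splice,
                                cis = design$planted_cis_pairs,
                                network_membership = net$membership,
                                nei = net$nei,
                                pathway = "pw_planted")
  config
}

#' Demo study: a planted design exercising every pipeline stage
#'
#' Builds the bundled demonstration dataset: 6 cases vs 5 controls, 200
#' coding genes and 20 lncRNAs, ten 4-fold DE genes concentrated in module
#' 1 of a 4x30 planted-partition network, a planted hub gene wired to its
#' whole module, a lncRNA cis-paired with the hub, five planted cassette
#' events, a planted enriched pathway, a module-1-biased reference gene
#' set, and qPCR shifts for three candidates.
#'
#' @param dir directory to write the dataset into.
#' @param seed master seed.
#' @return the [run_all()] configuration with planted truth attached.
#' @export
demo_config <- function(dir, seed = 1L) {
  de_genes <- sprintf("G%04d", 1:10)            # module 1 nodes
  fc <- stats::setNames(rep(c(4, -4), 5L), de_genes)
  ## the demonstration lncRNA is planted well above the calling threshold
  ## so the end-to-end walkthrough exercises wiring, not borderline power
  planted_de <- c(fc, L001 = -8)
  design <- simulation_design(
    seed = seed,
    planted_de = planted_de,
    planted_splice = data.frame(gene = sprintf("G%04d", 150:154),
                                label = "cassette exon", magnitude = 4,
                                exon_index = NA_integer_,
                                stringsAsFactors = FALSE),
    planted_cis_pairs = data.frame(lncrna = "L001", gene = "G0001",
                                   stringsAsFactors = FALSE),
    planted_trans_pairs = data.frame(lncrna = "L002", gene = "G0015",
                                     stringsAsFactors = FALSE),
    hub_gene = "G0001",
    planted_pathway = c(de_genes, sprintf("G%04d", 101:105)))
  write_dataset(design, dir)
}
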