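#' Feature annotation table
#'
#' Genomic intervals (1-based, closed) with a biotype per feature, used to
#' partition DE calls into coding/lncRNA classes and to drive cis-target
#' prediction.
#'
#' @param id,chrom,strand,start,end,biotype equal-length vectors;
#'   `biotype` must be `"coding"` or `"lncRNA"`; `start <= end` everywhere.
#' @return data frame of class `feature_annotation`.
#' @export
feature_annotation <- function(id, chrom, start, end,
                               strand = "+", biotype = "coding") {
  df <- data.frame(id = as.character(id), chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand),
                   biotype = as.character(biotype),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("feature ids must be unique")
  if (any(df$start > df$end)) stop("start must be <= end")
  if (!all(df$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'")
  class(df) <- c("feature_annotation", "data.frame")
  df
}

annotation_granges <- function(anno) {
  GenomicRanges::GRanges(
    seqnames = anno$chrom,
    ranges = IRanges::IRanges(start = anno$start, end = anno$end),
    strand = anno$strand, id = anno$id, biotype = anno$biotype)
}

#' Write annotation as GTF or BED
#'
#' GTF (1-based closed, carries `gene_biotype`) is the package's primary
#' on-disk annotation; BED (0-based half-open, converted by rtracklayer) is
#' provided for interoperability and drops the biotype into the name as
#' `id`.
#'
#' @param anno a [feature_annotation()].
#' @param path output file; format chosen by extension (`.gtf` / `.bed`).
#' @export
write_annotation <- function(anno, path) {
  gr <- annotation_granges(anno)
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$gene_id <- anno$id
    S4Vectors::mcols(gr)$gene_biotype <- anno$biotype
    rtracklayer::export(gr, path, format = "gtf")
  } else if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    names(gr) <- anno$id
    rtracklayer::export(gr, path, format = "bed")
  } else stop("unsupported annotation extension: ", path)
  invisible(path)
}

#' Read a feature annotation from GTF or BED
#'
#' @param path `.gtf` (biotype read from the `gene_biotype` attribute) or
#'   `.bed` (biotype from `lncrna_ids`, default coding).
#' @param lncrna_ids ids to mark as lncRNA when the format carries no
#'   biotype.
#' @return a [feature_annotation()].
#' @export
read_annotation <- function(path, lncrna_ids = character()) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (grepl("\\.gtf$", path, ignore.case = TRUE)) {
    id <- as.character(mc$gene_id)
    biotype <- as.character(mc$gene_biotype)
  } else {
    id <- as.character(mc$name)
    biotype <- ifelse(id %in% lncrna_ids, "lncRNA", "coding")
  }
  feature_annotation(id = id,
                     chrom = as.character(GenomeInfoDb::seqnames(gr)),
                     start = BiocGenerics::start(gr),
                     end = BiocGenerics::end(gr),
                     strand = as.character(BiocGenerics::strand(gr)),
                     biotype = biotype)
}

#' Predict cis-targets of lncRNAs
#'
#' A gene is a cis-target of a lncRNA when its interval intersects the
#' window stretching `window` bp beyond the lncRNA span on both sides
#' (closed-interval overlap on the same chromosome; strand is recorded but
#' ignored for the overlap).
#'
#' @param anno a [feature_annotation()] holding both coding genes and
#'   lncRNAs.
#' @param lncrnas ids of the lncRNAs to scan (default: every lncRNA in
#'   `anno`).
#' @param window flank size in bp (default 10 kb).
#' @return data frame `lncrna`, `gene`, `mode = "cis"`, `evidence` (the
#'   genomic gap in bp, 0 when the intervals themselves overlap).
#' @export
predict_cis <- function(anno, lncrnas = NULL, window = 10000L) {
  lnc <- anno[anno$biotype == "lncRNA", , drop = FALSE]
  if (!is.null(lncrnas)) lnc <- lnc[lnc$id %in% lncrnas, , drop = FALSE]
  genes <- anno[anno$biotype == "coding", , drop = FALSE]
  empty <- data.frame(lncrna = character(), gene = character(),
                      mode = character(), evidence = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(lnc) == 0L || nrow(genes) == 0L) return(empty)
  win <- GenomicRanges::GRanges(
    lnc$chrom,
    IRanges::IRanges(pmax(1L, lnc$start - as.integer(window)),
                     lnc$end + as.integer(window)))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(win, gg, ignore.strand = TRUE)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  gap <- pmax(0L,
              pmax(lnc$start[qi] - genes$end[si],
                   genes$start[si] - lnc$end[qi]) - 1L)
  out <- data.frame(lncrna = lnc$id[qi], gene = genes$id[si],
                    mode = "cis", evidence = as.numeric(gap),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

clean_rna <- function(s) {
  s <- chartr("acgtu", "ACGTU", s)
  s <- chartr("U", "T", s)
  if (any(grepl("[^ACGT]", s)))
    stop("sequences must be over the alphabet A, C, G, U/T")
  s
}

#' Screen lncRNAs for trans-targets by sequence complementarity
#'
#' Scores the best local alignment of each lncRNA against the reverse
#' complement of each candidate mRNA (match +1, mismatch -1, gap -2) and
#' emits a pair when the score reaches `score_threshold` -- by default 30,
#' i.e. a perfect 30-nt RNA-RNA duplex. The raw alignment score is the
#' evidence. This is a self-contained complementarity screen; externally
#' computed pair lists can be supplied to the pipeline instead.
#'
#' @param lnc_seqs,mrna_seqs named character vectors or
#'   `Biostrings::DNAStringSet`/`RNAStringSet` objects.
#' @param score_threshold minimum local alignment score.
#' @return data frame `lncrna`, `gene`, `mode = "trans"`, `evidence`
#'   (alignment score).
#' @export
predict_trans <- function(lnc_seqs, mrna_seqs, score_threshold = 30) {
  as_dna <- function(x) {
    if (methods::is(x, "XStringSet")) x <- as.character(x)
    Biostrings::DNAStringSet(clean_rna(x))
  }
  lnc <- as_dna(lnc_seqs); mrna <- as_dna(mrna_seqs)
  out <- data.frame(lncrna = character(), gene = character(),
                    mode = character(), evidence = numeric(),
                    stringsAsFactors = FALSE)
  if (length(lnc) == 0L || length(mrna) == 0L) return(out)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  rc <- Biostrings::reverseComplement(mrna)
  for (i in seq_along(lnc)) {
    sc <- Biostrings::pairwiseAlignment(
      rep(lnc[i], length(rc)), rc, type = "local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2,
      scoreOnly = TRUE)
    hit <- which(sc >= score_threshold)
    if (length(hit))
      out <- rbind(out, data.frame(lncrna = names(lnc)[i],
                                   gene = names(mrna)[hit],
                                   mode = "trans", evidence = sc[hit],
                                   stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
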