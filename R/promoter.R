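#' Extract the promoter region upstream of a start codon
#'
#' Takes the `maxLen` (default 2000) bases immediately upstream of the
#' start codon as the promoter, truncating at the chromosome edge and at
#' the nearest upstream annotated feature (exclusive of its proximal
#' boundary): a neighbouring ORF closer than `maxLen` shortens the
#' promoter accordingly. For a minus-strand gene the genomic bases
#' downstream of `cds_start` are taken and reverse-complemented, so the
#' returned sequence always reads 5'->3' toward the start codon.
#'
#' @param gene one-row data.frame (or list) with `gene_id`, `seq_id`,
#'   `strand` (`"+"`/`"-"`) and `cds_start` (1-based first base of the
#'   start codon on the biological sense strand).
#' @param genome a named `DNAStringSet` (or named character vector) of
#'   chromosome sequences containing `gene$seq_id`.
#' @param others data.frame of other annotated features with `seq_id`,
#'   `start`, `end` (1-based inclusive); used for truncation. May be
#'   empty or NULL.
#' @param maxLen maximum promoter length in bp (default 2000).
#' @return Length-1 named `DNAStringSet`; `S4Vectors::mcols()` carries
#'   `gene_id`, `length` and `truncated` (`TRUE` iff length < `maxLen`).
#' @examples
#' genome <- c(chr1 = paste(rep("ACGT", 750), collapse = ""))
#' gene <- data.frame(gene_id = "g1", seq_id = "chr1", strand = "+",
#'                    cds_start = 2001)
#' extractPromoter(gene, genome)
#' @export
extractPromoter <- function(gene, genome, others = NULL, maxLen = 2000) {
  stopifnot(maxLen >= 1)
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(toupper(genome))
  seqId <- as.character(gene$seq_id)
  if (!seqId %in% names(genome))
    stop("sequence ", seqId, " not found in genome", call. = FALSE)
  chrom <- genome[[seqId]]
  chrLen <- length(chrom)
  cds <- as.integer(gene$cds_start)
  strand <- as.character(gene$strand)
  stopifnot(strand %in% c("+", "-"), cds >= 1, cds <= chrLen)
  if (!is.null(others) && nrow(as.data.frame(others))) {
    others <- as.data.frame(others)
    others <- others[others$seq_id == seqId, , drop = FALSE]
  } else {
    others <- data.frame(seq_id = character(), start = integer(),
                         end = integer())
  }
  if (strand == "+") {
    lo <- max(cds - maxLen, 1L)
    up <- others$end[others$end < cds]
    if (length(up)) lo <- max(lo, max(up) + 1L)
    hi <- cds - 1L
    if (hi < lo)
      stop("gene ", gene$gene_id, ": zero-length promoter at ",
           "chromosome/feature boundary", call. = FALSE)
    prom <- Biostrings::DNAStringSet(Biostrings::subseq(chrom, lo, hi))
  } else {
    hi <- min(cds + maxLen, chrLen)
    down <- others$start[others$start > cds]
    if (length(down)) hi <- min(hi, min(down) - 1L)
    lo <- cds + 1L
    if (hi < lo)
      stop("gene ", gene$gene_id, ": zero-length promoter at ",
           "chromosome/feature boundary", call. = FALSE)
    prom <- Biostrings::DNAStringSet(Biostrings::reverseComplement(
      Biostrings::subseq(chrom, lo, hi)))
  }
  names(prom) <- as.character(gene$gene_id)
  len <- Biostrings::width(prom)
  S4Vectors::mcols(prom) <- S4Vectors::DataFrame(
    gene_id = as.character(gene$gene_id), length = len,
    truncated = len < maxLen)
  prom
}

#' Extract promoters for a whole annotation table
#'
#' Applies [extractPromoter()] to every gene of an annotation table; for
#' each gene, all *other* rows act as potential truncating upstream
#' features.
#'
#' @param annotation data.frame with columns `gene_id`, `seq_id`,
#'   `strand`, `cds_start`, `start`, `end`.
#' @param genome named `DNAStringSet` of chromosomes.
#' @param maxLen maximum promoter length (default 2000).
#' @return Named `DNAStringSet` of promoters with `mcols()` as in
#'   [extractPromoter()].
#' @export
extractPromoters <- function(annotation, genome, maxLen = 2000) {
  annotation <- as.data.frame(annotation)
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene ids in annotation", call. = FALSE)
  proms <- lapply(seq_len(nrow(annotation)), function(i)
    extractPromoter(annotation[i, ], genome,
                    others = annotation[-i, , drop = FALSE],
                    maxLen = maxLen))
  out <- do.call(c, proms)
  S4Vectors::mcols(out) <- do.call(rbind, lapply(proms, S4Vectors::mcols))
  out
}

#' Read a gene annotation table from GFF3
#'
#' Imports `gene` features and derives the fields the promoter extractor
#' needs: `cds_start` is the feature's biological start (GFF `start` on
#' `+`, `end` on `-`).
#'
#' @param path GFF3 file.
#' @param featureType feature type to keep (default `"gene"`).
#' @return data.frame with columns `gene_id`, `seq_id`, `strand`,
#'   `cds_start`, `start`, `end`.
#' @export
readAnnotationGFF3 <- function(path, featureType = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[as.character(gr$type) %in% featureType, , drop = FALSE]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
    as.character(gr$Name)
  strand <- as.character(gr$strand)
  if (any(!strand %in% c("+", "-")))
    stop("every feature must have a defined strand", call. = FALSE)
  data.frame(gene_id = ids,
             seq_id = as.character(gr$seqnames),
             strand = strand,
             cds_start = ifelse(strand == "+", gr$start, gr$end),
             start = gr$start, end = gr$end, stringsAsFactors = FALSE)
}
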