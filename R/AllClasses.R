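#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importClassesFrom Biostrings AAStringSet DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames SummarizedExperiment
#' @importFrom stats setNames sd runif rnorm
#' @importFrom utils head read.delim write.table
NULL

#' Scoring scheme for global protein alignment
#'
#' Parameterizes [alignGlobal()] and [percentSimilarity()]: residue pairs
#' score `match` when identical, `similar` when both fall in one of the
#' strong-conservation `groups`, and `mismatch` otherwise; gaps are affine
#' (a gap of length k scores `gapOpen + (k - 1) * gapExtend`).
#'
#' @slot match numeric score for identical residues.
#' @slot similar numeric score for residues sharing a conservation group.
#' @slot mismatch numeric score for all other residue pairs.
#' @slot gapOpen non-positive score of the first residue of a gap.
#' @slot gapExtend non-positive score of each further gap residue.
#' @slot groups character vector of conservation groups, each group a
#'   string of single-letter amino-acid codes (e.g. `"STA"`).
#' @export
setClass("ScoringScheme",
  representation(match = "numeric", similar = "numeric",
    mismatch = "numeric", gapOpen = "numeric", gapExtend = "numeric",
    groups = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@match >= object@similar && object@similar >= object@mismatch))
      msg <- c(msg, "must have match >= similar >= mismatch")
    if (!(object@gapOpen <= object@gapExtend && object@gapExtend <= 0))
      msg <- c(msg, "must have gapOpen <= gapExtend <= 0")
    if (length(msg)) msg else TRUE
  })

#' The classic strong-conservation amino-acid groups
#'
#' The conservative substitution sets used to call two aligned residues
#' "similar": STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW.
#' @export
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                   "MILV", "MILF", "HY", "FYW")

#' Construct a ScoringScheme
#'
#' @param match,similar,mismatch residue-pair scores (defaults 1, 0.5, 0).
#' @param gapOpen,gapExtend affine gap scores (defaults -10, -0.5); a gap of
#'   length k scores `gapOpen + (k - 1) * gapExtend`.
#' @param groups conservation groups; defaults to [STRONG_GROUPS].
#' @return A [ScoringScheme-class] object.
#' @examples
#' scoringScheme()
#' scoringScheme(groups = character()) # identity-only similarity
#' @export
scoringScheme <- function(match = 1, similar = 0.5, mismatch = 0,
                          gapOpen = -10, gapExtend = -0.5,
                          groups = STRONG_GROUPS) {
  new("ScoringScheme", match = match, similar = similar,
      mismatch = mismatch, gapOpen = gapOpen, gapExtend = gapExtend,
      groups = toupper(groups))
}

#' Pairwise global alignment of two protein sequences
#'
#' @slot alignedA,alignedB gapped aligned strings of equal length.
#' @slot score optimal alignment score under the scheme used.
#' @slot idA,idB sequence identifiers.
#' @export
setClass("PairwiseAlignment",
  representation(alignedA = "character", alignedB = "character",
    score = "numeric", idA = "character", idB = "character"),
  validity = function(object) {
    msg <- character()
    if (nchar(object@alignedA) != nchar(object@alignedB))
      msg <- c(msg, "aligned strings must have equal length")
    a <- strsplit(object@alignedA, "")[[1]]
    b <- strsplit(object@alignedB, "")[[1]]
    if (any(a == "-" & b == "-"))
      msg <- c(msg, "no column may be gap/gap")
    if (length(msg)) msg else TRUE
  })

#' A labelled reference panel of transporter proteins
#'
#' Known family members (e.g. characterized sucrose transporters and the
#' seven monosaccharide-transporter subfamilies I-VII) against which query
#' proteins are classified by best percent similarity.
#'
#' @slot sequences an [Biostrings::AAStringSet] with unique non-empty names.
#' @slot family character, `"SUC"` or `"MST"` per entry.
#' @slot subfamily character subfamily label per entry (e.g. `"I_STP"`).
#' @export
setClass("ReferencePanel",
  representation(sequences = "AAStringSet", family = "character",
    subfamily = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@sequences)
    if (n == 0L) msg <- c(msg, "panel must be non-empty")
    if (length(object@family) != n || length(object@subfamily) != n)
      msg <- c(msg, "family and subfamily labels must match sequence count")
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))
      msg <- c(msg, "sequences must carry unique non-empty names")
    if (any(is.na(object@subfamily)) || any(!nzchar(object@subfamily)))
      msg <- c(msg, "every entry must carry a subfamily label")
    if (length(msg)) msg else TRUE
  })

#' Construct a ReferencePanel
#'
#' @param sequences an `AAStringSet` (or named character vector) of
#'   reference proteins with unique names.
#' @param family character vector (`"SUC"`/`"MST"`), one per sequence.
#' @param subfamily character vector of subfamily labels, one per sequence.
#' @return A [ReferencePanel-class].
#' @export
referencePanel <- function(sequences, family, subfamily) {
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  new("ReferencePanel", sequences = sequences,
      family = as.character(family), subfamily = as.character(subfamily))
}

#' A library of IUPAC-degenerate cis-regulatory elements
#'
#' @slot motifs data.frame with columns `name` (unique), `iupac`
#'   (degenerate consensus over the 15 IUPAC nucleotide codes), `response`
#'   (annotation) and `source` (`table1`, `table2`, `text` or `user`).
#' @seealso [defaultMotifLibrary()] for the packaged library.
#' @export
setClass("MotifLibrary", representation(motifs = "data.frame"),
  validity = function(object) {
    m <- object@motifs
    msg <- character()
    req <- c("name", "iupac", "response", "source")
    if (!all(req %in% names(m)))
      return(paste("motifs must have columns", paste(req, collapse = ", ")))
    if (anyDuplicated(m$name)) msg <- c(msg, "motif names must be unique")
    if (any(!nzchar(m$iupac))) msg <- c(msg, "iupac strings must be non-empty")
    bad <- grepl(sprintf("[^%s]", IUPAC_CODES_STR), toupper(m$iupac))
    if (any(bad))
      msg <- c(msg, paste("invalid IUPAC string:", m$iupac[bad][1]))
    if (length(msg)) msg else TRUE
  })

#' Construct a MotifLibrary
#'
#' @param name,iupac,response,source equal-length character vectors (or a
#'   single data.frame in `name` holding those columns).
#' @return A [MotifLibrary-class].
#' @examples
#' motifLibrary(name = "GATABOX", iupac = "GATA",
#'              response = "Light, leaf, shoot", source = "table1")
#' @export
motifLibrary <- function(name, iupac = NULL, response = "", source = "user") {
  if (is.data.frame(name)) {
    df <- name
    if (is.null(df$response)) df$response <- ""
    if (is.null(df$source)) df$source <- "user"
  } else {
    df <- data.frame(name = as.character(name),
                     iupac = toupper(as.character(iupac)),
                     response = rep_len(as.character(response), length(name)),
                     source = rep_len(as.character(source), length(name)),
                     stringsAsFactors = FALSE)
  }
  df$iupac <- toupper(df$iupac)
  rownames(df) <- NULL
  new("MotifLibrary", motifs = df)
}

#' Promoter x motif copy-count matrix
#'
#' The central object of the cis-element analysis: `counts[g, m]` is the
#' number of (possibly overlapping) occurrences of motif `m` in the
#' promoter of gene `g`, on the strands recorded in `strands`.
#'
#' @slot counts non-negative integer matrix, genes x motifs, with dimnames.
#' @slot strands `"forward"` or `"both"`.
#' @export
setClass("OccurrenceTable",
  representation(counts = "matrix", strands = "character"),
  validity = function(object) {
    cnt <- object@counts
    msg <- character()
    if ((nrow(cnt) > 0 && is.null(rownames(cnt))) ||
        (ncol(cnt) > 0 && is.null(colnames(cnt))))
      msg <- c(msg, "counts must carry gene and motif dimnames")
    if (anyDuplicated(rownames(cnt)))
      msg <- c(msg, "duplicate gene ids in counts")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "counts must be finite non-negative integers")
    if (!object@strands %in% c("forward", "both"))
      msg <- c(msg, "strands must be 'forward' or 'both'")
    if (length(msg)) msg else TRUE
  })

#' Quantified spots of one macroarray membrane
#'
#' One hybridized membrane: spot-level raw signals and local backgrounds
#' for transporter genes, reference genes and negative-control spots, all
#' sharing one condition (organ or berry stage).
#'
#' @slot spots data.frame with columns `gene_id`, `membrane_id`,
#'   `spot_index`, `raw_signal`, `background`, `condition`.
#' @slot referenceGenes gene ids used for normalization (default actin,
#'   EF1a, EF1g, GAPDH).
#' @slot negativeControls gene ids of the negative-control spots
#'   (default salmon_sperm).
#' @export
setClass("MembraneExperiment",
  representation(spots = "data.frame", referenceGenes = "character",
    negativeControls = "character"),
  validity = function(object) {
    s <- object@spots
    msg <- character()
    req <- c("gene_id", "membrane_id", "spot_index", "raw_signal",
             "background", "condition")
    if (!all(req %in% names(s)))
      return(paste("spots must have columns", paste(req, collapse = ", ")))
    if (length(unique(s$membrane_id)) != 1L)
      msg <- c(msg, "a MembraneExperiment holds exactly one membrane")
    if (length(unique(s$condition)) != 1L)
      msg <- c(msg, "all spots on a membrane share one condition")
    if (any(s$raw_signal < 0) || any(s$background < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (any(s$spot_index < 1))
      msg <- c(msg, "spot_index must be >= 1")
    missRef <- setdiff(object@referenceGenes, s$gene_id)
    if (length(missRef))
      msg <- c(msg, paste("reference gene(s) missing from membrane:",
                          paste(missRef, collapse = ", ")))
    missNeg <- setdiff(object@negativeControls, s$gene_id)
    if (length(missNeg))
      msg <- c(msg, paste("negative control(s) missing from membrane:",
                          paste(missNeg, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' Construct a MembraneExperiment
#'
#' @param spots data.frame of one membrane's spots (see
#'   [MembraneExperiment-class]).
#' @param referenceGenes,negativeControls gene ids of the normalization
#'   references and negative-control spots present on the membrane.
#' @return A [MembraneExperiment-class].
#' @export
membraneExperiment <- function(spots,
    referenceGenes = c("actin", "EF1a", "EF1g", "GAPDH"),
    negativeControls = "salmon_sperm") {
  new("MembraneExperiment", spots = as.data.frame(spots),
      referenceGenes = referenceGenes, negativeControls = negativeControls)
}

#' Normalized gene x condition expression profile
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assays `mean`, `sd`,
#' `n` and `present`: per gene and condition, the mean and standard
#' deviation of the normalized spot replicates (relative units, reference
#' mean = 1), the replicate count, and the negative-control presence flag.
#' Genes absent on every membrane of a condition have mean 0.
#'
#' @export
setClass("ExpressionProfile", contains = "SummarizedExperiment",
  validity = function(object) {
    req <- c("mean", "sd", "n", "present")
    if (!all(req %in% SummarizedExperiment::assayNames(object)))
      return(paste("assays must include", paste(req, collapse = ", ")))
    mn <- SummarizedExperiment::assay(object, "mean")
    pr <- SummarizedExperiment::assay(object, "present")
    if (any(mn[!pr] != 0))
      return("mean must be 0 wherever present is FALSE")
    if (any(mn < 0)) return("means must be non-negative")
    TRUE
  })

#' Construct an ExpressionProfile
#'
#' @param mean,sd,n,present gene x condition matrices of identical
#'   dimensions (dimnames: genes x conditions).
#' @return An [ExpressionProfile-class].
#' @export
expressionProfile <- function(mean, sd, n, present) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(mean = mean, sd = sd, n = n, present = present))
  new("ExpressionProfile", se)
}
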