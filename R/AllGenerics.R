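#' @include AllClasses.R
NULL

#' Accessors for vitisugar classes
#'
#' Small accessor generics: `motifCounts()` returns the gene x motif count
#' matrix of an [OccurrenceTable-class]; `geneIds()` and `motifNames()` its
#' dimnames; `motifs()` the motif data.frame of a [MotifLibrary-class];
#' `panelSequences()`, `panelFamily()` and `panelSubfamily()` the slots of
#' a [ReferencePanel-class]; `spotData()` the spot table of a
#' [MembraneExperiment-class]; `conditionMeans()` the per-condition mean of
#' all gene means of an [ExpressionProfile-class] (the red-point
#' denominator).
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))
#' @rdname accessors
#' @export
setMethod("motifCounts", "OccurrenceTable", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setMethod("geneIds", "OccurrenceTable", function(x) rownames(x@counts))

#' @rdname accessors
#' @export
setGeneric("motifNames", function(x) standardGeneric("motifNames"))
#' @rdname accessors
#' @export
setMethod("motifNames", "OccurrenceTable", function(x) colnames(x@counts))
#' @rdname accessors
#' @export
setMethod("motifNames", "MotifLibrary", function(x) x@motifs$name)

#' @rdname accessors
#' @export
setGeneric("motifs", function(x) standardGeneric("motifs"))
#' @rdname accessors
#' @export
setMethod("motifs", "MotifLibrary", function(x) x@motifs)

#' @rdname accessors
#' @export
setGeneric("panelSequences", function(x) standardGeneric("panelSequences"))
#' @rdname accessors
#' @export
setMethod("panelSequences", "ReferencePanel", function(x) x@sequences)

#' @rdname accessors
#' @export
setGeneric("panelFamily", function(x) standardGeneric("panelFamily"))
#' @rdname accessors
#' @export
setMethod("panelFamily", "ReferencePanel", function(x) x@family)

#' @rdname accessors
#' @export
setGeneric("panelSubfamily", function(x) standardGeneric("panelSubfamily"))
#' @rdname accessors
#' @export
setMethod("panelSubfamily", "ReferencePanel", function(x) x@subfamily)

#' @rdname accessors
#' @export
setGeneric("spotData", function(x) standardGeneric("spotData"))
#' @rdname accessors
#' @export
setMethod("spotData", "MembraneExperiment", function(x) x@spots)

#' @rdname accessors
#' @export
setGeneric("conditionMeans", function(x) standardGeneric("conditionMeans"))
#' @rdname accessors
#' @export
setMethod("conditionMeans", "ExpressionProfile", function(x)
  colMeans(SummarizedExperiment::assay(x, "mean")))

#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setMethod("alignmentScore", "PairwiseAlignment", function(x) x@score)

#' @rdname accessors
#' @export
setGeneric("alignedStrings", function(x) standardGeneric("alignedStrings"))
#' @rdname accessors
#' @export
setMethod("alignedStrings", "PairwiseAlignment", function(x) {
  nm <- c(if (length(x@idA) && nzchar(x@idA[1])) x@idA[1] else "a",
          if (length(x@idB) && nzchar(x@idB[1])) x@idB[1] else "b")
  stats::setNames(c(x@alignedA, x@alignedB), nm)
})

setMethod("show", "ScoringScheme", function(object) {
  cat("ScoringScheme: match", object@match, "/ similar", object@similar,
      "/ mismatch", object@mismatch, "\n  gap open", object@gapOpen,
      ", extend", object@gapExtend, "\n  groups:",
      paste(object@groups, collapse = " "), "\n")
})

setMethod("show", "PairwiseAlignment", function(object) {
  cat("PairwiseAlignment (score ", format(object@score), ")\n",
      "  ", object@alignedA, "\n  ", object@alignedB, "\n", sep = "")
})

setMethod("show", "MotifLibrary", function(object) {
  cat("MotifLibrary with", nrow(object@motifs), "motifs\n")
  print(utils::head(object@motifs, 6))
  if (nrow(object@motifs) > 6) cat("  ...\n")
})

setMethod("show", "OccurrenceTable", function(object) {
  cat("OccurrenceTable:", nrow(object@counts), "promoters x",
      ncol(object@counts), "motifs (", object@strands, "strand )\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", length(object@sequences), "sequences,",
      length(unique(object@subfamily)), "subfamilies\n")
})

setMethod("show", "MembraneExperiment", function(object) {
  s <- object@spots
  cat("MembraneExperiment", unique(s$membrane_id), "(",
      unique(s$condition), "):", nrow(s), "spots,",
      length(unique(s$gene_id)), "genes\n")
})
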