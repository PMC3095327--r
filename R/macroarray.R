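#' Background-correct a spot intensity
#'
#' Subtracts the local background from the raw signal, clipping at zero
#' (negative corrected intensities are physically meaningless).
#'
#' @param raw_signal,background non-negative numeric vectors.
#' @return `pmax(raw_signal - background, 0)`.
#' @examples
#' correctBackground(500, 100) # 400
#' correctBackground(80, 100)  # 0
#' @export
correctBackground <- function(raw_signal, background) {
  if (any(raw_signal < 0) || any(background < 0))
    stop("intensities must be non-negative", call. = FALSE)
  pmax(raw_signal - background, 0)
}

#' Negative-control presence call
#'
#' A gene is called present only if the mean of its background-corrected
#' spot intensities is strictly greater than the mean of the
#' negative-control spots (salmon-sperm DNA in the original design).
#' Equality is absence.
#'
#' @param geneSpots corrected intensities of the gene's spots (>= 1).
#' @param negatives corrected intensities of the negative-control spots
#'   (>= 1).
#' @return Logical scalar.
#' @export
presenceCall <- function(geneSpots, negatives) {
  if (!length(geneSpots))
    stop("gene has no spots", call. = FALSE)
  if (!length(negatives))
    stop("need at least one negative-control spot", call. = FALSE)
  mean(geneSpots) > mean(negatives)
}

#' Normalize one membrane to its reference genes
#'
#' Background-corrects every spot, calls presence per gene against the
#' negative controls, and divides each spot by the membrane's reference
#' factor: the mean over the reference genes of their mean corrected
#' intensities. Genes failing the presence call are set to 0 and flagged
#' absent. All reference genes must themselves pass the presence call;
#' otherwise the membrane is unusable and an error names the failing
#' reference.
#'
#' @param m a [MembraneExperiment-class].
#' @return data.frame with one row per (non-control) spot: `gene_id`,
#'   `spot_index`, `rel` (normalized spot intensity; reference genes
#'   average 1 by construction), `present` (gene-level flag). Negative-
#'   control spots are excluded.
#' @export
normalizeMembrane <- function(m) {
  stopifnot(methods::is(m, "MembraneExperiment"))
  methods::validObject(m)
  s <- m@spots
  s$corrected <- correctBackground(s$raw_signal, s$background)
  negMean <- mean(s$corrected[s$gene_id %in% m@negativeControls])
  geneMeans <- tapply(s$corrected, s$gene_id, mean)
  present <- geneMeans > negMean
  absentRefs <- m@referenceGenes[!present[m@referenceGenes]]
  if (length(absentRefs))
    stop("reference gene(s) absent on membrane ",
         unique(s$membrane_id), ": ",
         paste(absentRefs, collapse = ", "), call. = FALSE)
  refFactor <- mean(geneMeans[m@referenceGenes])
  keep <- !s$gene_id %in% m@negativeControls
  out <- data.frame(gene_id = s$gene_id[keep],
                    spot_index = s$spot_index[keep],
                    rel = s$corrected[keep] / refFactor,
                    present = unname(present[s$gene_id[keep]]),
                    stringsAsFactors = FALSE)
  out$rel[!out$present] <- 0
  out
}

#' Aggregate normalized replicates into an expression value
#'
#' Pools the spot-level normalized values of one gene in one condition
#' across its replicate membranes (the original design: 3 spots x 2
#' independent membranes = 6 replicates) into mean, standard deviation
#' and replicate count. The gene is present if the presence call held on
#' at least one membrane; membranes on which it was absent contribute
#' zeros.
#'
#' @param relValues list of numeric vectors, one per membrane, of the
#'   gene's normalized spot values (zeros when absent on that membrane).
#' @param present logical vector, one per membrane: gene-level presence.
#' @return list with `mean`, `sd`, `n`, `present`.
#' @export
aggregateReplicates <- function(relValues, present) {
  stopifnot(length(relValues) >= 1, length(present) == length(relValues))
  if (length(relValues) == 1L)
    warning("single replicate membrane: n = ", length(relValues[[1]]),
            call. = FALSE)
  v <- unlist(relValues, use.names = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v), present = any(present))
}

#' Run the full macroarray quantification pipeline
#'
#' Splits a multi-membrane spot table by membrane, normalizes each
#' membrane independently to its own reference genes
#' ([normalizeMembrane()]), then pools the spot-level normalized values
#' per gene and condition across replicate membranes
#' ([aggregateReplicates()]).
#'
#' @param spots data.frame of spot rows over one or more membranes (see
#'   [readSpotTable()]).
#' @param referenceGenes,negativeControls as in [membraneExperiment()].
#' @return An [ExpressionProfile-class] over the non-control,
#'   non-reference genes; conditions ordered as first encountered.
#' @export
macroarrayProfile <- function(spots,
    referenceGenes = c("actin", "EF1a", "EF1g", "GAPDH"),
    negativeControls = "salmon_sperm") {
  spots <- as.data.frame(spots)
  membranes <- unique(spots$membrane_id)
  norm <- vector("list", length(membranes))
  conditionOf <- character(length(membranes))
  for (i in seq_along(membranes)) {
    sub <- spots[spots$membrane_id == membranes[i], , drop = FALSE]
    m <- membraneExperiment(sub, referenceGenes, negativeControls)
    norm[[i]] <- normalizeMembrane(m)
    conditionOf[i] <- unique(sub$condition)
  }
  genes <- setdiff(unique(spots$gene_id),
                   c(referenceGenes, negativeControls))
  conditions <- unique(conditionOf)
  dims <- list(genes, conditions)
  mn <- sdm <- nm <- matrix(0, length(genes), length(conditions),
                            dimnames = dims)
  pr <- matrix(FALSE, length(genes), length(conditions), dimnames = dims)
  for (cond in conditions) {
    idx <- which(conditionOf == cond)
    if (length(idx) == 1L)
      warning("condition ", cond, ": single membrane only",
              call. = FALSE)
    for (g in genes) {
      rels <- lapply(idx, function(i) {
        nm_i <- norm[[i]]
        nm_i$rel[nm_i$gene_id == g]
      })
      pres <- vapply(idx, function(i) {
        nm_i <- norm[[i]]
        any(nm_i$present[nm_i$gene_id == g])
      }, logical(1))
      agg <- suppressWarnings(aggregateReplicates(rels, pres))
      mn[g, cond] <- agg$mean
      sdm[g, cond] <- agg$sd
      nm[g, cond] <- agg$n
      pr[g, cond] <- agg$present
    }
  }
  expressionProfile(mean = mn, sd = sdm, n = nm, present = pr)
}

#' High-expression (red-point) calls
#'
#' Flags, per condition, each gene whose mean expression is strictly
#' greater than the mean over all genes' means in that condition — the
#' "red point" rule of the original membrane figures. Absent genes count
#' as zeros in the condition mean.
#'
#' @param p an [ExpressionProfile-class] with >= 2 genes.
#' @return Logical gene x condition matrix.
#' @export
callHigh <- function(p) {
  stopifnot(methods::is(p, "ExpressionProfile"))
  mn <- SummarizedExperiment::assay(p, "mean")
  if (nrow(mn) < 2L)
    stop("need at least 2 genes per condition", call. = FALSE)
  cm <- colMeans(mn)
  sweep(mn, 2, cm, ">")
}

#' Preferential-expression summary
#'
#' Condenses an expression profile into the qualitative summary of the
#' original study's closing figure: per condition, the genes above the
#' condition mean ([callHigh()]); the most-expressed gene(s) (the "bold"
#' analogue; restricted to above-mean genes so a flat profile yields
#' none); genes preferentially expressed in a condition (mean >= `fold` x
#' the gene's mean across all conditions); and, when `stages` gives an
#' ordered developmental series, genes induced over development
#' (non-decreasing across the stages with final >= `fold` x first).
#'
#' @param p an [ExpressionProfile-class] with >= 2 conditions.
#' @param fold fold-change threshold (> 1; default 2).
#' @param stages optional character vector of condition names in
#'   developmental order.
#' @return list of class `PreferentialSummary`: `above_mean` and
#'   `preferential` (logical gene x condition matrices),
#'   `most_expressed` (list of gene ids per condition), `induced`
#'   (named logical per gene; all-NA list absent when `stages` is NULL),
#'   `fold`, `stages`.
#' @export
summarizePreferential <- function(p, fold = 2.0, stages = NULL) {
  stopifnot(methods::is(p, "ExpressionProfile"))
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  mn <- SummarizedExperiment::assay(p, "mean")
  if (ncol(mn) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  high <- callHigh(p)
  mostExpressed <- lapply(colnames(mn), function(cond) {
    v <- mn[, cond]
    top <- rownames(mn)[v == max(v)]
    intersect(top, rownames(mn)[high[, cond]])
  })
  names(mostExpressed) <- colnames(mn)
  geneMeans <- rowMeans(mn)
  preferential <- mn >= fold * geneMeans
  preferential[geneMeans == 0, ] <- FALSE
  induced <- NULL
  if (!is.null(stages)) {
    missing <- setdiff(stages, colnames(mn))
    if (length(missing))
      stop("unknown stage(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    sm <- mn[, stages, drop = FALSE]
    induced <- apply(sm, 1, function(v)
      all(diff(v) >= 0) && v[length(v)] >= fold * v[1] && v[length(v)] > 0)
  }
  structure(list(above_mean = high, most_expressed = mostExpressed,
                 preferential = preferential, induced = induced,
                 fold = fold, stages = stages),
            class = "PreferentialSummary")
}

#' @export
print.PreferentialSummary <- function(x, ...) {
  cat("PreferentialSummary (fold =", x$fold, ")\n")
  for (cond in colnames(x$above_mean)) {
    above <- rownames(x$above_mean)[x$above_mean[, cond]]
    cat(" ", cond, ": above mean:",
        if (length(above)) paste(above, collapse = ", ") else "(none)",
        "| most expressed:",
        if (length(x$most_expressed[[cond]]))
          paste(x$most_expressed[[cond]], collapse = ", ") else "(none)",
        "\n")
  }
  invisible(x)
}

#' Single-reference (Northern-style) normalization
#'
#' Divides every gene's signal by the signal of one reference gene
#' (GAPDH in the original RNA gel-blot validation); the reference maps
#' to 1.
#'
#' @param signals named numeric vector of per-gene intensities.
#' @param reference name of the reference gene; must be present with a
#'   strictly positive signal.
#' @return Named numeric vector of ratios.
#' @examples
#' northernNormalize(c(g1 = 330, GAPDH = 100), "GAPDH")
#' @export
northernNormalize <- function(signals, reference = "GAPDH") {
  if (!reference %in% names(signals))
    stop("reference gene ", reference, " absent from signals",
         call. = FALSE)
  ref <- signals[[reference]]
  if (!is.finite(ref) || ref <= 0)
    stop("reference signal must be > 0", call. = FALSE)
  signals / ref
}
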