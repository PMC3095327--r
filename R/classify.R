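#' Cis-elements common to (nearly) all promoters
#'
#' A motif is "common" when it occurs at least once in all but at most
#' `toleranceMissing` of the analyzed promoters. For each common motif the
#' maximum copy number over promoters and the promoters missing it are
#' reported. The default tolerance is 0 (strictly conserved); a tolerance
#' of a few genes accommodates short truncated promoters that drop a
#' handful of otherwise universal elements.
#'
#' @param tab an [OccurrenceTable-class].
#' @param toleranceMissing maximum number of promoters allowed to lack
#'   the motif (default 0).
#' @return data.frame with columns `motif`, `max_copies`, `n_missing`,
#'   `missing_genes` (","-separated; empty string when none).
#' @export
classifyCommon <- function(tab, toleranceMissing = 0) {
  cnt <- motifCounts(tab)
  stopifnot(nrow(cnt) >= 1, toleranceMissing >= 0)
  keep <- colSums(cnt == 0) <= toleranceMissing
  res <- data.frame(
    motif = colnames(cnt)[keep],
    max_copies = if (any(keep)) apply(cnt[, keep, drop = FALSE], 2, max)
                 else integer(),
    n_missing = colSums(cnt[, keep, drop = FALSE] == 0),
    missing_genes = vapply(which(keep), function(m)
      paste(rownames(cnt)[cnt[, m] == 0], collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Cis-elements unique to a single promoter
#'
#' Motifs occurring in exactly one of the analyzed promoters, implying
#' gene-specific regulation. Requires at least two promoters (uniqueness
#' is undefined for one).
#'
#' @param tab an [OccurrenceTable-class] over >= 2 promoters.
#' @return data.frame with columns `motif`, `gene_id`, `copies`.
#' @export
classifyUnique <- function(tab) {
  cnt <- motifCounts(tab)
  if (nrow(cnt) < 2L)
    stop("uniqueness is undefined for a single promoter", call. = FALSE)
  nz <- colSums(cnt > 0)
  keep <- which(nz == 1L)
  res <- data.frame(
    motif = colnames(cnt)[keep],
    gene_id = vapply(keep, function(m) rownames(cnt)[cnt[, m] > 0],
                     character(1)),
    copies = vapply(keep, function(m) max(cnt[, m]), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Cis-elements restricted to one gene family
#'
#' Motifs whose occurrences all fall in promoters of a single family,
#' with at least two such promoters (a motif in exactly one promoter is
#' "unique", not "restricted"; see [classifyUnique()]).
#'
#' @param tab an [OccurrenceTable-class].
#' @param families named character vector mapping every gene id in `tab`
#'   to its family label (e.g. `"SUC"`).
#' @return data.frame with columns `motif`, `family`, `n_genes`.
#' @export
familyRestricted <- function(tab, families) {
  cnt <- motifCounts(tab)
  unmapped <- setdiff(rownames(cnt), names(families))
  if (length(unmapped))
    stop("gene(s) without a family label: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  fam <- families[rownames(cnt)]
  keep <- integer()
  famOut <- character()
  nOut <- integer()
  for (m in seq_len(ncol(cnt))) {
    carriers <- fam[cnt[, m] > 0]
    if (length(carriers) >= 2L && length(unique(carriers)) == 1L) {
      keep <- c(keep, m)
      famOut <- c(famOut, unique(carriers))
      nOut <- c(nOut, length(carriers))
    }
  }
  data.frame(motif = colnames(cnt)[keep], family = famOut,
             n_genes = nOut, stringsAsFactors = FALSE)
}

#' Sugar-responsive motif repertory per promoter
#'
#' For a chosen set of sugar-responsive motifs, counts per gene the
#' number of DISTINCT motifs present (copy count >= 1) and returns the
#' genes ranked by that number, together with the per-motif copy counts.
#'
#' @param tab an [OccurrenceTable-class].
#' @param sugarMotifs character vector of motif names; must all be
#'   columns of `tab`.
#' @return list with `ranking` (data.frame `gene_id`, `n_distinct`,
#'   sorted decreasing, ties in input gene order) and `counts` (the
#'   gene x sugar-motif count submatrix).
#' @export
sugarRepertory <- function(tab, sugarMotifs) {
  cnt <- motifCounts(tab)
  unknown <- setdiff(sugarMotifs, colnames(cnt))
  if (length(unknown))
    stop("unknown motif name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub <- cnt[, sugarMotifs, drop = FALSE]
  nd <- rowSums(sub > 0)
  ord <- order(-nd)
  list(ranking = data.frame(gene_id = rownames(cnt)[ord],
                            n_distinct = unname(nd[ord]),
                            stringsAsFactors = FALSE),
       counts = sub)
}

#' Detect a composite cis-element (e.g. a GARC complex)
#'
#' Flags each promoter that carries every component of a composite
#' element, such as the gibberellin-response complex (AMYBOX1 + AMYBOX2 +
#' pyrimidine box). No spacing constraint is applied: co-occurrence
#' anywhere in the promoter suffices.
#'
#' @param tab an [OccurrenceTable-class].
#' @param components non-empty character vector of motif names, all
#'   columns of `tab`.
#' @param rule currently only `"all_present"`.
#' @return Named logical vector, one element per gene.
#' @export
detectComposite <- function(tab, components, rule = "all_present") {
  rule <- match.arg(rule, "all_present")
  if (!length(components))
    stop("component set must be non-empty", call. = FALSE)
  cnt <- motifCounts(tab)
  unknown <- setdiff(components, colnames(cnt))
  if (length(unknown))
    stop("unknown component name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  res <- rowSums(cnt[, components, drop = FALSE] > 0) == length(components)
  stats::setNames(as.logical(res), rownames(cnt))
}
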