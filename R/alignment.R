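#' @useDynLib vitisugar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.lutCache <- new.env(parent = emptyenv())

# 256x256 substitution lookup indexed by raw character codes, built from a
# ScoringScheme. Identity scores `match` even for letters outside any group.
# Memoized: rebuilding it for every pairwise call dominates otherwise.
substitutionLookup <- function(scheme) {
  key <- paste(scheme@match, scheme@similar, scheme@mismatch,
               paste(sort(scheme@groups), collapse = "|"), sep = "#")
  if (!is.null(.lutCache[[key]])) return(.lutCache[[key]])
  lut <- buildSubstitutionLookup(scheme)
  .lutCache[[key]] <- lut
  lut
}

buildSubstitutionLookup <- function(scheme) {
  alphabet <- c(LETTERS, "*")
  lut <- matrix(scheme@mismatch, 256, 256)
  idx <- utf8ToInt(paste(alphabet, collapse = "")) + 1L
  grp <- lapply(scheme@groups, function(g) strsplit(g, "")[[1]])
  for (a in alphabet) {
    ia <- utf8ToInt(a) + 1L
    for (b in alphabet) {
      ib <- utf8ToInt(b) + 1L
      if (a == b) {
        lut[ia, ib] <- scheme@match
      } else if (any(vapply(grp, function(g) a %in% g && b %in% g, TRUE))) {
        lut[ia, ib] <- scheme@similar
      }
    }
  }
  lut
}

asResidueString <- function(x, what = "sequence") {
  if (methods::is(x, "XString") || methods::is(x, "XStringSet")) {
    if (methods::is(x, "XStringSet")) {
      stopifnot(length(x) == 1L)
      x <- x[[1]]
    }
    x <- as.character(x)
  }
  x <- toupper(as.character(x)[1])
  if (is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty sequence", call. = FALSE)
  x
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch-Gotoh global alignment with affine gaps under a
#' [ScoringScheme-class]. Traceback ties are broken deterministically,
#' preferring diagonal over up (gap in `b`) over left (gap in `a`).
#'
#' @param a,b sequences (character, `AAString`, or length-1 `AAStringSet`);
#'   must be non-empty.
#' @param scheme a [ScoringScheme-class]; default [scoringScheme()].
#' @return A [PairwiseAlignment-class] with the aligned gapped strings and
#'   the optimal score.
#' @examples
#' alignGlobal("ACDE", "ACE")
#' @export
alignGlobal <- function(a, b, scheme = scoringScheme()) {
  ida <- if (!is.null(names(a))) names(a)[1] else ""
  idb <- if (!is.null(names(b))) names(b)[1] else ""
  sa <- asResidueString(a, "sequence a")
  sb <- asResidueString(b, "sequence b")
  res <- gotoh_align(sa, sb, substitutionLookup(scheme),
                     scheme@gapOpen, scheme@gapExtend)
  new("PairwiseAlignment", alignedA = res$aligned_a,
      alignedB = res$aligned_b, score = res$score,
      idA = ida, idB = idb)
}

#' Percent similarity of an aligned sequence pair
#'
#' The fraction of alignment columns in which both residues are present
#' (no gap) and are identical or fall within one strong-conservation
#' group, relative to the length of the shorter of the two (degapped)
#' sequences, times 100. Self-alignments therefore score 100, and a short
#' sequence fully contained in a longer one can also reach 100.
#'
#' @param aln a [PairwiseAlignment-class].
#' @param scheme the [ScoringScheme-class] whose `groups` define
#'   similarity.
#' @return Percent in `[0, 100]`.
#' @export
percentSimilarity <- function(aln, scheme = scoringScheme()) {
  stopifnot(methods::is(aln, "PairwiseAlignment"))
  ca <- utf8ToInt(aln@alignedA)
  cb <- utf8ToInt(aln@alignedB)
  gap <- utf8ToInt("-")
  res <- ca != gap & cb != gap
  simL <- similarOrIdenticalLookup(scheme)
  hits <- sum(simL[cbind(ca[res] + 1L, cb[res] + 1L)])
  shorter <- min(sum(ca != gap), sum(cb != gap))
  100 * hits / shorter
}

.simCache <- new.env(parent = emptyenv())

# 256x256 logical lookup: TRUE where two residue codes are identical or
# share a strong-conservation group.
similarOrIdenticalLookup <- function(scheme) {
  key <- paste0("g:", paste(sort(scheme@groups), collapse = "|"))
  if (!is.null(.simCache[[key]])) return(.simCache[[key]])
  lut <- matrix(FALSE, 256, 256)
  codes <- utf8ToInt(paste(c(LETTERS, "*"), collapse = "")) + 1L
  lut[cbind(codes, codes)] <- TRUE
  for (g in scheme@groups) {
    gc <- utf8ToInt(g) + 1L
    lut[as.matrix(expand.grid(gc, gc))] <- TRUE
  }
  .simCache[[key]] <- lut
  lut
}

#' All-pairs percent-similarity matrix
#'
#' Aligns every unordered pair once with [alignGlobal()] and fills a
#' symmetric matrix of [percentSimilarity()] values with diagonal 100.
#'
#' @param seqs an `AAStringSet` (or named character vector) of at least
#'   two sequences with unique ids.
#' @param scheme a [ScoringScheme-class].
#' @return Symmetric numeric matrix of percents in `[0, 100]`, labelled by
#'   sequence id, diagonal 100.
#' @export
similarityMatrix <- function(seqs, scheme = scoringScheme()) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must carry unique ids", call. = FALSE)
  chars <- as.character(seqs)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- alignGlobal(chars[i], chars[j], scheme)
      m[i, j] <- m[j, i] <- percentSimilarity(aln, scheme)
    }
  }
  m
}
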