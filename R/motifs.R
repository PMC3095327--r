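#' @include AllClasses.R
NULL

# IUPAC nucleotide ambiguity codes and the concrete bases each allows.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

IUPAC_CODES_STR <- paste(names(IUPAC_SETS), collapse = "")

#' Compile an IUPAC-degenerate motif into a position-set matcher
#'
#' Expands each symbol of the consensus into its allowed-base set
#' (R = A/G, Y = C/T, W = A/T, M = A/C, K = G/T, S = C/G, B/D/H/V the
#' three-base sets, N = any). Ambiguity codes in the *scanned* sequence
#' are treated conservatively: they never satisfy a motif position except
#' under motif-N, which matches any character.
#'
#' @param iupac consensus string over the 15 IUPAC nucleotide codes.
#' @return An object of class `CompiledMotif`: a list with the consensus,
#'   its length and the per-position allowed-character sets.
#' @examples
#' compileMotif("GRWAAW")
#' @export
compileMotif <- function(iupac) {
  iupac <- toupper(as.character(iupac)[1])
  sym <- strsplit(iupac, "")[[1]]
  if (!length(sym)) stop("motif must be non-empty", call. = FALSE)
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC symbol: ", bad[1], call. = FALSE)
  sets <- lapply(sym, function(s) {
    if (s == "N") names(IUPAC_SETS) else IUPAC_SETS[[s]]
  })
  structure(list(iupac = iupac, width = length(sym), sets = sets),
            class = "CompiledMotif")
}

#' @export
print.CompiledMotif <- function(x, ...) {
  cat("CompiledMotif", x$iupac, "(width", x$width, ")\n")
  invisible(x)
}

#' Enumerate the concrete words of an IUPAC consensus
#'
#' @param iupac consensus string.
#' @return Character vector of every concrete A/C/G/T word the consensus
#'   matches (cartesian product of the position sets, N contributing the
#'   four bases).
#' @examples
#' expandMotif("GRWAAW") # 8 words
#' @export
expandMotif <- function(iupac) {
  sym <- strsplit(toupper(iupac), "")[[1]]
  bad <- setdiff(sym, names(IUPAC_SETS))
  if (length(bad)) stop("invalid IUPAC symbol: ", bad[1], call. = FALSE)
  sets <- IUPAC_SETS[sym]
  apply(expand.grid(rev(sets), stringsAsFactors = FALSE), 1,
        function(r) paste(rev(r), collapse = ""))
}

reverseComplement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
            D = "H", H = "D", N = "N")
  s <- rev(strsplit(toupper(x), "")[[1]])
  out <- comp[s]
  out[is.na(out)] <- s[is.na(out)]
  paste(out, collapse = "")
}

# Match starts of a compiled motif on a literal character vector.
matchStarts <- function(chars, cm) {
  n <- length(chars)
  k <- cm$width
  if (n < k) return(integer())
  ok <- rep(TRUE, n - k + 1L)
  for (j in seq_len(k)) {
    ok <- ok & chars[seq.int(j, n - k + j)] %in% cm$sets[[j]]
  }
  which(ok)
}

#' Scan a promoter for an IUPAC motif
#'
#' Reports every (possibly overlapping) start position whose window
#' matches the motif. Under `strands = "both"` the reverse complement of
#' the promoter is scanned as well and each minus-strand hit is reported
#' as a (start, strand) pair, the start being the leftmost base of the
#' matching window in forward coordinates; self-complementary matches are
#' deliberately counted on both strands.
#'
#' @param promoter a DNA sequence (character, `DNAString`, or length-1
#'   named `DNAStringSet`).
#' @param motif an IUPAC string, a `CompiledMotif`, or a motif name
#'   present in `lib`.
#' @param strands `"forward"` (default) or `"both"`.
#' @param lib optional [MotifLibrary-class] used to resolve a motif name.
#' @param gene_id id recorded in the hit table; taken from `names()` when
#'   available.
#' @return data.frame with columns `motif`, `gene_id`, `start`, `strand`;
#'   zero rows when the motif is longer than the sequence.
#' @examples
#' scanMotif("GATAGATA", "GATA")      # starts 1 and 5
#' scanMotif("AGATTCGATT", "NGATT")   # starts 1 and 6
#' @export
scanMotif <- function(promoter, motif, strands = c("forward", "both"),
                      lib = NULL, gene_id = NULL) {
  strands <- match.arg(strands)
  if (is.null(gene_id)) {
    gene_id <- if (!is.null(names(promoter))) names(promoter)[1] else "seq"
  }
  if (methods::is(promoter, "XStringSet")) promoter <- promoter[[1]]
  if (methods::is(promoter, "XString")) promoter <- as.character(promoter)
  promoter <- toupper(promoter)
  cm <- if (inherits(motif, "CompiledMotif")) {
    motif
  } else if (!is.null(lib) && motif %in% motifNames(lib)) {
    compileMotif(motifs(lib)$iupac[match(motif, motifNames(lib))])
  } else {
    compileMotif(motif)
  }
  motifLabel <- if (is.character(motif) && !is.null(lib) &&
                    motif %in% motifNames(lib)) motif else cm$iupac
  chars <- strsplit(promoter, "")[[1]]
  fwd <- matchStarts(chars, cm)
  hits <- data.frame(motif = character(), gene_id = character(),
                     start = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  if (length(fwd))
    hits <- data.frame(motif = motifLabel, gene_id = gene_id,
                       start = fwd, strand = "+", stringsAsFactors = FALSE)
  if (strands == "both") {
    rcChars <- strsplit(reverseComplement(promoter), "")[[1]]
    rc <- matchStarts(rcChars, cm)
    if (length(rc)) {
      n <- length(chars)
      hits <- rbind(hits, data.frame(
        motif = motifLabel, gene_id = gene_id,
        start = n - (rc + cm$width - 1L) + 1L, strand = "-",
        stringsAsFactors = FALSE))
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Build the promoter x motif occurrence table
#'
#' Counts motif occurrences for every promoter/motif combination via
#' [scanMotif()].
#'
#' @param promoters a named `DNAStringSet` (or named character vector) of
#'   promoter sequences; names are gene ids and must be unique.
#' @param lib a [MotifLibrary-class].
#' @param strands `"forward"` (default) or `"both"`.
#' @return An [OccurrenceTable-class].
#' @export
occurrenceTable <- function(promoters, lib, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  stopifnot(methods::is(lib, "MotifLibrary"))
  if (methods::is(promoters, "XStringSet")) {
    seqs <- as.character(promoters)
  } else {
    seqs <- toupper(as.character(promoters))
    names(seqs) <- names(promoters)
  }
  if (!length(seqs)) stop("need at least one promoter", call. = FALSE)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    stop("promoters must carry unique gene ids", call. = FALSE)
  ml <- motifs(lib)
  compiled <- lapply(ml$iupac, compileMotif)
  counts <- matrix(0L, length(seqs), nrow(ml),
                   dimnames = list(ids, ml$name))
  for (g in seq_along(seqs)) {
    chars <- strsplit(toupper(seqs[g]), "")[[1]]
    rcChars <- if (strands == "both")
      strsplit(reverseComplement(seqs[g]), "")[[1]] else NULL
    for (m in seq_along(compiled)) {
      n <- length(matchStarts(chars, compiled[[m]]))
      if (!is.null(rcChars))
        n <- n + length(matchStarts(rcChars, compiled[[m]]))
      counts[g, m] <- n
    }
  }
  new("OccurrenceTable", counts = counts, strands = strands)
}

#' The packaged cis-regulatory element library
#'
#' The 30 elements whose consensus strings this pipeline ships: the 20
#' common elements (source `table1`, carrying their reported maximum
#' copies per promoter as the `response`-adjacent annotation), the 9
#' single-gene elements (source `table2`), and the sugar/ABA S-box
#' CACCTCCA (source `text`). Further elements (SURE boxes, sucrose box 3,
#' AMY boxes, pyrimidine-box variants, ...) must be supplied by the user
#' via [readMotifLibrary()].
#'
#' @return A [MotifLibrary-class] with 30 motifs.
#' @export
defaultMotifLibrary <- function() {
  path <- system.file("extdata", "motif_library.json",
                      package = "vitisugar", mustWork = TRUE)
  readMotifLibrary(path)
}
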