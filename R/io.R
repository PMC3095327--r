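VALID_DNA <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
VALID_PROTEIN <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Read and validate a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] with the validation this pipeline
#' relies on: ids must be unique and non-empty, residues are upper-cased
#' and checked against the declared alphabet (IUPAC nucleotide codes for
#' `"dna"`; the 20 amino acids plus X for `"protein"`).
#'
#' @param path FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A `DNAStringSet` or `AAStringSet`; empty set for an empty
#'   file. Wrapped sequence lines are concatenated; record order is
#'   preserved.
#' @export
readFastaRecords <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  raw <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    stop("FASTA record with empty id", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", dup[1], call. = FALSE)
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence: ",
         ids[!nzchar(seqs)][1], call. = FALSE)
  valid <- if (alphabet == "dna") VALID_DNA else VALID_PROTEIN
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!chars %in% valid)
    if (length(bad))
      stop("record ", ids[i], ": residue '", chars[bad[1]],
           "' at position ", bad[1], " outside the ", alphabet,
           " alphabet", call. = FALSE)
  }
  out <- if (alphabet == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param x a named `XStringSet` (or named character vector).
#' @param path output file.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
writeFastaRecords <- function(x, path, width = 70L) {
  if (!methods::is(x, "XStringSet")) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

SPOT_COLUMNS <- c("gene_id", "membrane_id", "spot_index", "raw_signal",
                  "background", "condition")

#' Read a macroarray spot-intensity table
#'
#' Reads a TSV with one row per quantified spot and validates it: the six
#' required columns must be present, intensities numeric and
#' non-negative, spot indices integer and >= 1.
#'
#' @param path TSV file with header `gene_id`, `membrane_id`,
#'   `spot_index`, `raw_signal`, `background`, `condition`.
#' @return data.frame of typed spot rows.
#' @export
readSpotTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing))
    stop("spot table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, SPOT_COLUMNS]
  for (col in c("spot_index", "raw_signal", "background")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("non-numeric value in column ", col, call. = FALSE)
    df[[col]] <- v
  }
  if (any(df$raw_signal < 0) || any(df$background < 0))
    stop("negative intensity in spot table", call. = FALSE)
  if (any(df$spot_index < 1) || any(df$spot_index != round(df$spot_index)))
    stop("spot_index must be an integer >= 1", call. = FALSE)
  df$spot_index <- as.integer(df$spot_index)
  df
}

#' Write a spot table as TSV
#' @param spots data.frame of spot rows.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  utils::write.table(spots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] with >= 2 leaves, branch lengths set and
#'   non-empty leaf labels.
#' @param path optional output file; when NULL the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file). The
#'   string terminates with ";" and round-trips through
#'   [readNewickTree()].
#' @export
writeNewickTree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L)
    stop("tree must have at least 2 leaves", call. = FALSE)
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("every leaf must carry a non-empty label", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("branch lengths must be set", call. = FALSE)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#' @param x a file path or a Newick string.
#' @return An [ape::phylo].
#' @export
readNewickTree <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}

#' Read a motif library from JSON
#'
#' The interchange format is a JSON array of objects with fields `name`,
#' `iupac`, `response` and `source`.
#'
#' @param path JSON file.
#' @return A [MotifLibrary-class].
#' @export
readMotifLibrary <- function(path) {
  df <- jsonlite::fromJSON(path)
  motifLibrary(df)
}

#' Write a motif library to JSON
#' @param lib a [MotifLibrary-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMotifLibrary <- function(lib, path) {
  stopifnot(methods::is(lib, "MotifLibrary"))
  jsonlite::write_json(motifs(lib), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}
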