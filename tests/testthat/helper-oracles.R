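# Independent oracles used across the suite. These deliberately share no
# code with the package internals: the aligner oracle enumerates every
# monotone alignment recursively, and the motif oracle expands the
# degenerate word set and counts windows with the regex engine.

# Exhaustive enumeration of all global alignments of a and b under an
# affine gap model (gap of length k costs open + (k-1) * extend),
# returning the optimal score. Exponential; for short sequences only.
bruteAlignScore <- function(a, b, scheme) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  grp <- lapply(scheme@groups, function(g) strsplit(g, "")[[1]])
  subScore <- function(x, y) {
    if (x == y) return(scheme@match)
    if (any(vapply(grp, function(g) x %in% g && y %in% g, TRUE)))
      return(scheme@similar)
    scheme@mismatch
  }
  n <- length(ac)
  m <- length(bc)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- subScore(ac[i], bc[j]) + rec(i + 1, j + 1, "M")
      if (s > best) best <- s
    }
    if (i <= n) {
      g <- if (last == "X") scheme@gapExtend else scheme@gapOpen
      s <- g + rec(i + 1, j, "X")
      if (s > best) best <- s
    }
    if (j <= m) {
      g <- if (last == "Y") scheme@gapExtend else scheme@gapOpen
      s <- g + rec(i, j + 1, "Y")
      if (s > best) best <- s
    }
    best
  }
  rec(1, 1, "start")
}

# Expand an IUPAC consensus into its concrete words (local map, recursive
# product), then count every (overlapping) window occurrence of any word
# with a lookahead regex.
oracleIupacSets <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleExpand <- function(iupac) {
  sym <- strsplit(iupac, "")[[1]]
  words <- ""
  for (s in sym) {
    words <- as.vector(outer(words, oracleIupacSets[[s]], paste0))
  }
  words
}

oracleMotifCount <- function(seq, iupac) {
  total <- 0L
  for (w in oracleExpand(iupac)) {
    m <- gregexpr(paste0("(?=", w, ")"), seq, perl = TRUE)[[1]]
    if (m[1] != -1L) total <- total + length(m)
  }
  total
}

oracleRevComp <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small deterministic spot table: one membrane, one condition.
makeSpots <- function(membrane = "m1", condition = "leaf",
                      genes = c(t1 = 200, t2 = 50),
                      refs = c(actin = 400, EF1a = 500, EF1g = 450,
                               GAPDH = 650),
                      neg = 100, spotsPerGene = 3, background = 10,
                      scale = 1) {
  levels <- c(genes, refs, salmon_sperm = neg)
  data.frame(
    gene_id = rep(names(levels), each = spotsPerGene),
    membrane_id = membrane,
    spot_index = rep(seq_len(spotsPerGene), times = length(levels)),
    raw_signal = (rep(unname(levels), each = spotsPerGene) + background) *
      scale,
    background = background * scale,
    condition = condition, stringsAsFactors = FALSE)
}
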