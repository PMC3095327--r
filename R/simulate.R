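AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Derive a per-stream sub-seed from a root seed
#'
#' Mixes a root seed with a stream label so that each generator consumes
#' an independent, reproducible stream: adding a generator never
#' perturbs the draws of another. The result stays below 2^31.
#'
#' @param seed integer root seed.
#' @param stream character stream label (e.g. `"promoters"`).
#' @return Integer sub-seed.
#' @export
deriveSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 1234567) %% 2147483647)
}

#' Simulate promoter sequences with planted motifs
#'
#' Generates `nPromoters` background sequences and plants IUPAC motif
#' copies at known, non-overlapping positions, emitting the planted
#' copy-number matrix as ground truth. Under the `poly_c` background any
#' motif requiring a non-C base cannot occur by chance, so the truth
#' matrix equals exactly what [occurrenceTable()] reports; under the
#' random backgrounds chance hits come on top of the planted ones.
#'
#' @param nPromoters number of promoters.
#' @param length promoter length in bp (default 2000, the upstream
#'   window the pipeline analyzes).
#' @param background `"poly_c"`, `"uniform_acgt"` or `"fixed_gc"`.
#' @param plants data.frame with columns `motif` (a name in `lib`),
#'   `gene` (promoter index) and `copies`; NULL plants nothing.
#' @param lib a [MotifLibrary-class] (default the packaged library);
#'   defines the truth-matrix columns and resolves planted motif names.
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @param gc GC fraction for `fixed_gc` (default 0.5).
#' @param margin minimum number of background bases separating planted
#'   instances (default 10, at least the widest packaged motif): keeps
#'   two abutting planted words from composing a spurious third motif,
#'   so planted-truth equality is deterministic on poly-C backgrounds.
#' @return list with `promoters` (named `DNAStringSet`, genes `P01`,
#'   `P02`, ...) and `truth` (integer gene x motif matrix of planted
#'   copies).
#' @export
simulatePromoters <- function(nPromoters, length = 2000,
    background = c("poly_c", "uniform_acgt", "fixed_gc"),
    plants = NULL, lib = defaultMotifLibrary(), seed = 1, gc = 0.5,
    margin = 10L) {
  background <- match.arg(background)
  stopifnot(nPromoters >= 1, length >= 1)
  set.seed(deriveSeed(seed, "promoters"))
  ids <- sprintf("P%02d", seq_len(nPromoters))
  ml <- motifs(lib)
  truth <- matrix(0L, nPromoters, nrow(ml), dimnames = list(ids, ml$name))
  probs <- switch(background,
    uniform_acgt = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
    fixed_gc = c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2),
    poly_c = c(A = 0, C = 1, G = 0, T = 0))
  seqs <- vapply(seq_len(nPromoters), function(i)
    paste(sample(names(probs), length, replace = TRUE, prob = probs),
          collapse = ""), character(1))
  if (!is.null(plants) && nrow(plants)) {
    plants <- as.data.frame(plants)
    if (any(!plants$motif %in% ml$name))
      stop("planted motif not in library: ",
           setdiff(plants$motif, ml$name)[1], call. = FALSE)
    for (g in unique(plants$gene)) {
      pg <- plants[plants$gene == g & plants$copies > 0, , drop = FALSE]
      if (!nrow(pg)) next
      widths <- rep(nchar(ml$iupac[match(pg$motif, ml$name)]), pg$copies)
      motifIdx <- rep(match(pg$motif, ml$name), pg$copies)
      if (sum(widths + margin) - margin > length)
        stop("planted motifs cannot fit without overlap in promoter ",
             g, call. = FALSE)
      starts <- placeNonOverlapping(widths, length, margin = margin)
      chars <- strsplit(seqs[g], "")[[1]]
      for (k in seq_along(starts)) {
        word <- sampleConcreteWord(ml$iupac[motifIdx[k]])
        chars[seq.int(starts[k], starts[k] + widths[k] - 1L)] <-
          strsplit(word, "")[[1]]
      }
      seqs[g] <- paste(chars, collapse = "")
      for (m in unique(motifIdx))
        truth[g, m] <- truth[g, m] + sum(motifIdx == m)
    }
  }
  proms <- Biostrings::DNAStringSet(seqs)
  names(proms) <- ids
  list(promoters = proms, truth = truth)
}

# Draw start positions for windows of the given widths on [1, seqLen],
# separated pairwise by at least `margin` background bases. The windows
# are laid out in random left-to-right order with the remaining slack
# distributed uniformly among the gaps, so placement always succeeds
# when the windows fit.
placeNonOverlapping <- function(widths, seqLen, margin = 0L) {
  k <- length(widths)
  ord <- sample.int(k)
  w <- widths[ord]
  slack <- seqLen - sum(w) - margin * (k - 1L)
  if (slack < 0)
    stop("could not place planted motifs without overlap", call. = FALSE)
  lead <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
  offsets <- c(0L, cumsum(w[-k] + margin))
  starts <- integer(k)
  starts[ord] <- lead + offsets + 1L
  starts
}

# Draw one concrete word from a degenerate consensus.
sampleConcreteWord <- function(iupac) {
  sets <- IUPAC_SETS[strsplit(toupper(iupac), "")[[1]]]
  paste(vapply(sets, function(s)
    s[sample.int(base::length(s), 1L)], character(1)), collapse = "")
}

#' Simulate macroarray membranes from a known expression matrix
#'
#' Emulates the membrane design the quantification pipeline assumes:
#' per condition, `membranesPerCondition` independently exposed
#' membranes each carrying `spotsPerGene` spots per gene, four reference
#' genes and negative-control spots. Spot signal is
#' `exposure x level x lognormal(cv)` plus an additive local background
#' that is also recorded in the `background` column, so background
#' subtraction recovers the noisy signal exactly. A gene's absolute
#' level is `truth[g, c] x mean(referenceLevels)`: the pipeline's
#' reference normalization then returns `truth[g, c]` itself, exactly at
#' `noiseCV = 0`. The log-normal factor has unit mean
#' (`sigma = sqrt(log(1 + cv^2))`, mu = -sigma^2/2).
#'
#' @param truth non-negative gene x condition matrix in relative units
#'   (rownames genes, colnames conditions).
#' @param referenceLevels four positive reference-gene levels, named
#'   (default actin, EF1a, EF1g, GAPDH).
#' @param negativeLevel non-negative level of the negative-control
#'   spots; in relative units the implied detection threshold is
#'   `negativeLevel / mean(referenceLevels)`.
#' @param exposure positive per-membrane scale factors, recycled across
#'   each condition's membranes (default `c(1, 1.5)`).
#' @param noiseCV coefficient of variation of the multiplicative spot
#'   noise; must be in `[0, 1)`.
#' @param spotsPerGene,membranesPerCondition design constants (defaults
#'   3 and 2: six replicates per gene and condition).
#' @param seed integer seed.
#' @return list with `spots` (data.frame in [readSpotTable()] schema),
#'   `truth`, `referenceGenes` and `negativeControls`.
#' @export
simulateMembranes <- function(truth,
    referenceLevels = c(actin = 800, EF1a = 1000, EF1g = 900,
                        GAPDH = 1300),
    negativeLevel = 40, exposure = c(1, 1.5), noiseCV = 0.1,
    spotsPerGene = 3L, membranesPerCondition = 2L, seed = 1) {
  stopifnot(is.matrix(truth), all(truth >= 0),
            !is.null(rownames(truth)), !is.null(colnames(truth)))
  if (any(exposure <= 0))
    stop("exposure must be positive", call. = FALSE)
  if (noiseCV < 0 || noiseCV >= 1)
    stop("noiseCV must be in [0, 1)", call. = FALSE)
  stopifnot(length(referenceLevels) == 4, all(referenceLevels > 0),
            negativeLevel >= 0)
  set.seed(deriveSeed(seed, "membranes"))
  sigma <- sqrt(log(1 + noiseCV^2))
  refScale <- mean(referenceLevels)
  negId <- "salmon_sperm"
  exposure <- rep_len(exposure, membranesPerCondition)
  rows <- list()
  for (ci in seq_len(ncol(truth))) {
    cond <- colnames(truth)[ci]
    for (mi in seq_len(membranesPerCondition)) {
      memId <- sprintf("%s_m%d", cond, mi)
      ex <- exposure[mi]
      levels <- c(truth[, ci] * refScale, referenceLevels,
                  stats::setNames(negativeLevel, negId))
      ids <- rep(names(levels), each = spotsPerGene)
      lv <- rep(unname(levels), each = spotsPerGene)
      nSpot <- length(ids)
      noise <- if (noiseCV == 0) rep(1, nSpot) else
        exp(stats::rnorm(nSpot, -sigma^2 / 2, sigma))
      bg <- stats::runif(nSpot, 0.5, 1.5) * ex
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = ids, membrane_id = memId,
        spot_index = rep(seq_len(spotsPerGene), times = length(levels)),
        raw_signal = ex * lv * noise + bg, background = bg,
        condition = cond, stringsAsFactors = FALSE)
    }
  }
  spots <- do.call(rbind, rows)
  rownames(spots) <- NULL
  list(spots = spots, truth = truth,
       referenceGenes = names(referenceLevels),
       negativeControls = negId)
}

#' Simulate a labelled synthetic reference panel
#'
#' Builds a synthetic [ReferencePanel-class]: one random ancestor
#' protein per subfamily, each member derived from its ancestor by i.i.d.
#' substitutions at `withinDivergence`. The default subfamilies are the
#' sucrose transporters plus the seven monosaccharide-transporter
#' subfamilies I-VII.
#'
#' @param subfamilies character vector of subfamily labels.
#' @param membersPerSubfamily members per subfamily (default 2).
#' @param length protein length (default 200).
#' @param withinDivergence per-site substitution rate within a subfamily
#'   (default 0.05).
#' @param seed integer seed.
#' @return A [ReferencePanel-class]; entries named
#'   `<subfamily>_<member>`.
#' @export
simulatePanel <- function(
    subfamilies = c("SUC", "I_STP", "II_TMT", "III_PMT", "IV_ERD6",
                    "V_VGT", "VI_INT", "VII_pGlcT_SGB1"),
    membersPerSubfamily = 2L, length = 200L, withinDivergence = 0.05,
    seed = 1) {
  stopifnot(length >= 1, membersPerSubfamily >= 1,
            withinDivergence >= 0, withinDivergence <= 0.5)
  set.seed(deriveSeed(seed, "panel"))
  seqs <- character()
  subs <- character()
  for (sf in subfamilies) {
    anc <- paste(sample(AA20, length, replace = TRUE), collapse = "")
    for (k in seq_len(membersPerSubfamily)) {
      seqs[sprintf("%s_%d", sf, k)] <- mutateProtein(anc, withinDivergence)
      subs <- c(subs, sf)
    }
  }
  referencePanel(Biostrings::AAStringSet(seqs),
                 family = ifelse(subs == "SUC", "SUC", "MST"),
                 subfamily = subs)
}

# i.i.d. substitution of each site with probability `rate`, drawing a
# uniformly chosen different amino acid.
mutateProtein <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate diverged query proteins from a reference panel
#'
#' Each query is derived from a uniformly chosen panel member by i.i.d.
#' substitutions at `rate` per site; the source subfamily is recorded as
#' ground truth. A random additive tree over the panel ids is emitted
#' alongside, for distance-tree recovery checks. Rates above 0.5 are
#' rejected: assignment becomes unidentifiable.
#'
#' @param panel a [ReferencePanel-class].
#' @param rate per-site substitution probability in `[0, 0.5]`.
#' @param nQueries number of queries (default 500).
#' @param seed integer seed.
#' @return list with `queries` (`AAStringSet`, names `Q0001`, ...),
#'   `truth` (data.frame `query_id`, `source_id`, `subfamily`) and
#'   `tree` (a random [ape::phylo] over the panel ids with positive
#'   branch lengths).
#' @export
simulateFamily <- function(panel, rate = 0.1, nQueries = 500L, seed = 1) {
  stopifnot(methods::is(panel, "ReferencePanel"))
  if (rate < 0 || rate > 0.5)
    stop("substitution rate must be in [0, 0.5]", call. = FALSE)
  set.seed(deriveSeed(seed, "family"))
  refChars <- as.character(panel@sequences)
  ids <- names(panel@sequences)
  src <- sample.int(length(ids), nQueries, replace = TRUE)
  queries <- vapply(src, function(i) mutateProtein(refChars[i], rate),
                    character(1))
  names(queries) <- sprintf("Q%04d", seq_len(nQueries))
  tree <- ape::rtree(length(ids), tip.label = sample(ids),
                     br = function(n) stats::runif(n, 0.1, 1))
  tree <- ape::unroot(tree)
  list(queries = Biostrings::AAStringSet(queries),
       truth = data.frame(query_id = names(queries),
                          source_id = ids[src],
                          subfamily = panel@subfamily[src],
                          stringsAsFactors = FALSE),
       tree = tree)
}
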