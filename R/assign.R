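#' Assign query proteins to transporter subfamilies
#'
#' Best-hit classification against a labelled [ReferencePanel-class]: each
#' query is globally aligned to every panel entry and assigned the
#' subfamily of the entry with maximal [percentSimilarity()]. The margin
#' to the best hit in any other subfamily is reported. Queries whose best
#' similarity falls below `minSimilarity` are returned as `"unassigned"`
#' (not an error); a tie across subfamilies at machine precision yields an
#' `"ambiguous"` result carrying both candidates.
#'
#' @param queries an `AAStringSet` (or named character vector) of query
#'   proteins.
#' @param panel a [ReferencePanel-class].
#' @param scheme a [ScoringScheme-class].
#' @param minSimilarity assignment gate in percent; default 30, below the
#'   lowest within-family similarity seen in practice for these families.
#' @return A data.frame with one row per query: `query_id`, `subfamily`
#'   (NA when unassigned/ambiguous), `best_reference`, `best_similarity`,
#'   `margin` (NA when the panel holds a single subfamily), `status`
#'   (`assigned`, `unassigned` or `ambiguous`) and `candidates`
#'   (";"-separated subfamilies, for ambiguous results).
#' @examples
#' pan <- simulatePanel(membersPerSubfamily = 1, length = 60, seed = 1)
#' assignSubfamily(panelSequences(pan)[1], pan)
#' @export
assignSubfamily <- function(queries, panel, scheme = scoringScheme(),
                            minSimilarity = 30) {
  stopifnot(methods::is(panel, "ReferencePanel"))
  methods::validObject(panel)
  if (!methods::is(queries, "AAStringSet"))
    queries <- Biostrings::AAStringSet(queries)
  if (is.null(names(queries)))
    names(queries) <- paste0("query_", seq_along(queries))
  refChars <- as.character(panel@sequences)
  refIds <- names(panel@sequences)
  sub <- panel@subfamily
  out <- vector("list", length(queries))
  eps <- 1e-9
  for (k in seq_along(queries)) {
    q <- as.character(queries[[k]])
    sims <- vapply(refChars, function(r)
      percentSimilarity(alignGlobal(q, r, scheme), scheme), numeric(1))
    best <- which.max(sims)
    bestSim <- sims[best]
    bestSub <- sub[best]
    other <- sub != bestSub
    margin <- if (any(other)) bestSim - max(sims[other]) else NA_real_
    tied <- unique(sub[sims >= bestSim - eps])
    status <- "assigned"
    subfam <- bestSub
    if (bestSim < minSimilarity) {
      status <- "unassigned"
      subfam <- NA_character_
    } else if (length(tied) > 1L) {
      status <- "ambiguous"
      subfam <- NA_character_
    }
    out[[k]] <- data.frame(
      query_id = names(queries)[k], subfamily = subfam,
      best_reference = refIds[best], best_similarity = unname(bestSim),
      margin = unname(margin), status = status,
      candidates = paste(tied, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
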