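#' Neighbor-joining tree of a transporter family
#'
#' Builds an unrooted distance tree from a percent-similarity matrix (as
#' produced by [similarityMatrix()]) or directly from a distance matrix.
#' Similarities are transformed to distances as `d = (100 - s) / 100`,
#' with no multiple-hit correction: the tree is a descriptive summary of
#' pairwise similarity, not an evolutionary estimate. Negative branch
#' lengths occasionally produced by neighbor joining are clamped to zero
#' with the deficit moved to the sister branch, preserving the distance
#' between the two siblings. Additive input distances are reproduced
#' exactly by path lengths on the tree.
#'
#' @param x a symmetric labelled matrix: a percent-similarity matrix
#'   (diagonal 100) or a distance matrix (diagonal 0), or a `dist`.
#' @param type `"auto"` (default; decided from the diagonal),
#'   `"similarity"` or `"distance"`.
#' @return An [ape::phylo] tree whose tip labels are the matrix labels.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' njTree(d)
#' @export
njTree <- function(x, type = c("auto", "similarity", "distance")) {
  type <- match.arg(type)
  if (inherits(x, "dist")) x <- as.matrix(x)
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  if (nrow(x) < 3L)
    stop("need at least 3 labels to build a tree", call. = FALSE)
  if (is.null(rownames(x)))
    stop("matrix must carry labels", call. = FALSE)
  if (type == "auto")
    type <- if (all(abs(diag(x) - 100) < 1e-9)) "similarity" else "distance"
  d <- if (type == "similarity") (100 - x) / 100 else x
  if (any(!is.finite(d)) || any(d < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  tree <- ape::nj(stats::as.dist(d))
  clampNegativeBranches(tree)
}

# Zero out negative branch lengths, moving each deficit onto the sister
# branch so the sibling-to-sibling path length is preserved. Each edge is
# treated once; any residual deficit on an already-visited edge is dropped
# at zero rather than bounced back and forth.
clampNegativeBranches <- function(tree) {
  visited <- rep(FALSE, length(tree$edge.length))
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    if (!visited[e]) {
      parent <- tree$edge[e, 1]
      sib <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sib))
        tree$edge.length[sib[1]] <-
          tree$edge.length[sib[1]] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
    visited[e] <- TRUE
  }
  tree
}
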