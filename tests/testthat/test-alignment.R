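scheme <- scoringScheme()
plainScheme <- scoringScheme(groups = character())

test_that("self-alignment is gapless with full match score", {
  a <- alignGlobal("ACDE", "ACDE", scheme)
  s <- alignedStrings(a)
  expect_equal(unname(s[1]), "ACDE")
  expect_equal(unname(s[2]), "ACDE")
  expect_equal(alignmentScore(a), 4)
  expect_equal(percentSimilarity(a, scheme), 100)
})

test_that("a deletion opens one gap and matches the enumeration oracle", {
  a <- alignGlobal("ACDE", "ACE", scheme)
  expect_equal(alignmentScore(a), bruteAlignScore("ACDE", "ACE", scheme))
  s <- alignedStrings(a)
  expect_equal(sum(strsplit(unname(s[2]), "")[[1]] == "-"), 1)
})

test_that("empty sequences are rejected", {
  expect_error(alignGlobal("", "ACD"), "non-empty")
  expect_error(alignGlobal("ACD", ""), "non-empty")
})

test_that("percent similarity counts residue columns over the shorter length", {
  # T is not in any group once groups are disabled: 3/4 columns.
  a <- alignGlobal("AAAA", "AAAT", plainScheme)
  expect_equal(percentSimilarity(a, plainScheme), 75)
  # Contained sequence: denominator is the shorter sequence.
  b <- alignGlobal("AAAA", "AA", plainScheme)
  expect_equal(percentSimilarity(b, plainScheme), 100)
  # Under the default groups S/T/A are one conservation group.
  d <- alignGlobal("AAAA", "AAAT", scheme)
  expect_equal(percentSimilarity(d, scheme), 100)
})

test_that("percent similarity is symmetric and 100 iff group-identical", {
  set.seed(42)
  for (k in 1:20) {
    n1 <- sample(3:12, 1)
    n2 <- sample(3:12, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, TRUE), collapse = "")
    pab <- percentSimilarity(alignGlobal(a, b, plainScheme), plainScheme)
    pba <- percentSimilarity(alignGlobal(b, a, plainScheme), plainScheme)
    expect_equal(pab, pba)
    expect_gte(pab, 0)
    expect_lte(pab, 100)
  }
  expect_equal(
    percentSimilarity(alignGlobal("MKLV", "MKLV", plainScheme),
                      plainScheme), 100)
  expect_lt(
    percentSimilarity(alignGlobal("MKLV", "MKLW", plainScheme),
                      plainScheme), 100)
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  # All ordered pairs of length <= 3 words over {A,C,G,T}; the affine
  # dialect (first gap residue costs open) must agree exactly.
  words <- unlist(lapply(1:3, function(k)
    apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1, paste,
          collapse = "")))
  set.seed(7)
  pairs <- expand.grid(a = words, b = words, stringsAsFactors = FALSE)
  pairs <- pairs[sample(nrow(pairs), 300), ]
  for (i in seq_len(nrow(pairs))) {
    expect_equal(
      alignmentScore(alignGlobal(pairs$a[i], pairs$b[i], scheme)),
      bruteAlignScore(pairs$a[i], pairs$b[i], scheme),
      info = paste(pairs$a[i], pairs$b[i]))
  }
})

test_that("similarity matrix is symmetric with diagonal 100 and matches
           element-wise recomputation", {
  seqs <- c(s1 = "MKTAYIAK", s2 = "MKTAYIAR", s3 = "GGGGCCCC")
  m <- similarityMatrix(seqs, scheme)
  expect_equal(diag(m), c(s1 = 100, s2 = 100, s3 = 100))
  expect_equal(m, t(m))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(m[i, j], percentSimilarity(
      alignGlobal(seqs[i], seqs[j], scheme), scheme))
  }
  expect_equal(unname(similarityMatrix(c(a = "MKT", b = "MKT"))[1, 2]), 100)
  expect_error(similarityMatrix(c(a = "MKT")), "at least 2")
  expect_error(similarityMatrix(stats::setNames(c("MKT", "MKA"),
                                                c("a", "a"))), "unique")
})

test_that("scoring scheme validity is enforced", {
  expect_error(scoringScheme(match = 0, similar = 1), "match")
  expect_error(scoringScheme(gapOpen = 1), "gap")
  expect_error(scoringScheme(gapOpen = -1, gapExtend = -2), "gap")
})
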