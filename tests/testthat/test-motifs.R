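test_that("motif compilation expands IUPAC codes and rejects bad symbols", {
  cm <- compileMotif("GRWAAW")
  expect_equal(cm$width, 6)
  expect_length(expandMotif("GRWAAW"), 8)
  expect_equal(expandMotif("GATA"), "GATA")
  expect_error(compileMotif("GAXA"), "invalid IUPAC symbol: X")
  # product rule: CANNTG = 1*1*4*4*1*1 = 16 words
  expect_length(expandMotif("CANNTG"), 16)
})

test_that("scanning finds all overlapping forward hits", {
  h <- scanMotif("GATAGATA", "GATA")
  expect_equal(h$start, c(1, 5))
  h2 <- scanMotif("AGATTCGATT", "NGATT")
  expect_equal(h2$start, c(1, 6))
  expect_equal(nrow(scanMotif("ACG", "GATAA")), 0)
  # overlapping self-similar motif
  expect_equal(scanMotif("AAAAA", "AAA")$start, 1:3)
})

test_that("sequence ambiguity codes only match motif-N", {
  expect_equal(nrow(scanMotif("GANA", "GATA")), 0)
  expect_equal(nrow(scanMotif("GANA", "GAYA")), 0)
  expect_equal(scanMotif("GANA", "GANA")$start, 1)
  expect_equal(scanMotif("GGNA", "GGNA")$start, 1)
})

test_that("both-strand scanning reports (start, strand) pairs in forward
           coordinates", {
  # TGAC on the minus strand of GTCA (revcomp = TGAC)
  h <- scanMotif("GTCA", "TGAC", strands = "both")
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 1)
  # palindromic word is counted on both strands, by design
  hp <- scanMotif("GTCGAC", "GTCGAC", strands = "both")
  expect_equal(nrow(hp), 2)
  expect_setequal(hp$strand, c("+", "-"))
})

test_that("scan counts equal the regex expansion oracle on random DNA", {
  set.seed(101)
  lib <- motifs(defaultMotifLibrary())
  for (rep in 1:30) {
    seq <- randomDna(300)
    for (m in sample(nrow(lib), 8)) {
      expect_equal(nrow(scanMotif(seq, lib$iupac[m])),
                   oracleMotifCount(seq, lib$iupac[m]),
                   info = lib$name[m])
      both <- nrow(scanMotif(seq, lib$iupac[m], strands = "both"))
      oracleBoth <- oracleMotifCount(seq, lib$iupac[m]) +
        oracleMotifCount(oracleRevComp(seq), lib$iupac[m])
      expect_equal(both, oracleBoth, info = paste("both", lib$name[m]))
    }
  }
})

test_that("both-strand totals are invariant under reverse complement", {
  set.seed(55)
  lib <- defaultMotifLibrary()
  seqs <- stats::setNames(vapply(1:5, function(i) randomDna(400),
                                 character(1)), paste0("P", 1:5))
  rc <- stats::setNames(vapply(seqs, oracleRevComp, character(1)),
                        names(seqs))
  t1 <- motifCounts(occurrenceTable(seqs, lib, strands = "both"))
  t2 <- motifCounts(occurrenceTable(rc, lib, strands = "both"))
  expect_equal(colSums(t1), colSums(t2))
})

test_that("occurrence table equals per-cell scanMotif recomputation", {
  set.seed(77)
  lib <- defaultMotifLibrary()
  seqs <- stats::setNames(vapply(1:4, function(i) randomDna(250),
                                 character(1)), paste0("P", 1:4))
  tab <- occurrenceTable(seqs, lib)
  cnt <- motifCounts(tab)
  ml <- motifs(lib)
  for (g in names(seqs)) for (m in sample(nrow(ml), 6)) {
    expect_equal(cnt[g, ml$name[m]],
                 nrow(scanMotif(seqs[[g]], ml$iupac[m])))
  }
  expect_error(occurrenceTable(stats::setNames(c("ACGT", "ACGT"),
                                               c("a", "a")), lib),
               "unique")
})

test_that("poly-C promoters yield all-zero rows for non-C motifs", {
  lib <- defaultMotifLibrary()
  seqs <- stats::setNames(rep(strrep("C", 500), 2), c("P1", "P2"))
  cnt <- motifCounts(occurrenceTable(seqs, lib))
  expect_true(all(cnt == 0))
})

test_that("appending sequence never decreases counts", {
  set.seed(31)
  lib <- defaultMotifLibrary()
  base <- randomDna(200)
  ext <- paste0(base, randomDna(100))
  c1 <- motifCounts(occurrenceTable(c(P1 = base), lib))
  c2 <- motifCounts(occurrenceTable(c(P1 = ext), lib))
  expect_true(all(c2 >= c1))
})
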