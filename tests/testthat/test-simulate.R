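test_that("promoter generation is bit-reproducible and matches its truth", {
  lib <- defaultMotifLibrary()
  plants <- data.frame(motif = c("GATABOX", "GATABOX", "SBOX"),
                       gene = c(1, 1, 3), copies = c(2, 1, 2))
  s1 <- simulatePromoters(6, 400, "poly_c", plants = plants, seed = 42)
  s2 <- simulatePromoters(6, 400, "poly_c", plants = plants, seed = 42)
  expect_identical(as.character(s1$promoters), as.character(s2$promoters))
  expect_identical(s1$truth, s2$truth)
  expect_equal(s1$truth["P01", "GATABOX"], 3L)
  expect_equal(s1$truth["P03", "SBOX"], 2L)
  # On poly-C background the scanner reproduces the planted truth exactly
  tab <- occurrenceTable(s1$promoters, lib)
  expect_equal(motifCounts(tab), s1$truth)
})

test_that("impossible plantings and empty plantings are handled", {
  expect_error(
    simulatePromoters(2, 20, "poly_c",
                      plants = data.frame(motif = "CIACADIANLELHC",
                                          gene = 1, copies = 5), seed = 1),
    "fit|overlap")
  s <- simulatePromoters(3, 100, "poly_c",
                         plants = data.frame(motif = "GATABOX", gene = 1,
                                             copies = 0), seed = 1)
  expect_true(all(s$truth == 0))
})

test_that("different backgrounds have the stated composition", {
  s <- simulatePromoters(2, 500, "poly_c", seed = 1)
  expect_true(all(strsplit(as.character(s$promoters[[1]]), "")[[1]] == "C"))
  g <- simulatePromoters(2, 2000, "fixed_gc", gc = 0.8, seed = 1)
  chars <- strsplit(as.character(g$promoters[[1]]), "")[[1]]
  expect_gt(mean(chars %in% c("G", "C")), 0.75)
})

test_that("membrane simulation is reproducible and respects its contracts", {
  truth <- matrix(c(0.2, 0.4, 0.1, 0.3), 2, 2,
                  dimnames = list(c("g1", "g2"), c("a", "b")))
  s1 <- simulateMembranes(truth, seed = 6)
  s2 <- simulateMembranes(truth, seed = 6)
  expect_identical(s1$spots, s2$spots)
  expect_equal(nrow(s1$spots), 2 * 2 * (2 + 4 + 1) * 3)
  expect_error(simulateMembranes(truth, exposure = c(0, 1)), "positive")
  expect_error(simulateMembranes(truth, noiseCV = 1), "noiseCV")
})

test_that("exposure differences cancel out at zero noise", {
  truth <- matrix(runif(12, 0.1, 0.5), 4, 3,
                  dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  s1 <- simulateMembranes(truth, noiseCV = 0, exposure = c(1, 1), seed = 2)
  s3 <- simulateMembranes(truth, noiseCV = 0, exposure = c(1, 3), seed = 2)
  p1 <- macroarrayProfile(s1$spots)
  p3 <- macroarrayProfile(s3$spots)
  expect_equal(SummarizedExperiment::assay(p1, "mean"),
               SummarizedExperiment::assay(p3, "mean"), tolerance = 1e-12)
})

test_that("truth below the detection threshold is reported absent", {
  # threshold = negativeLevel / mean(referenceLevels) = 40/1000 = 0.04
  truth <- matrix(c(0.01, 0.2), 2, 1,
                  dimnames = list(c("low", "hi"), "leaf"))
  s <- simulateMembranes(truth, referenceLevels = c(actin = 800,
      EF1a = 1000, EF1g = 900, GAPDH = 1300), negativeLevel = 40,
      noiseCV = 0, seed = 3)
  p <- macroarrayProfile(s$spots)
  expect_false(SummarizedExperiment::assay(p, "present")["low", "leaf"])
  expect_equal(SummarizedExperiment::assay(p, "mean")["low", "leaf"], 0)
  expect_true(SummarizedExperiment::assay(p, "present")["hi", "leaf"])
})

test_that("family simulation derives queries from labelled sources", {
  pan <- simulatePanel(membersPerSubfamily = 2, length = 80, seed = 5)
  f0 <- simulateFamily(pan, rate = 0, nQueries = 10, seed = 5)
  src <- as.character(panelSequences(pan))[f0$truth$source_id]
  expect_equal(as.character(f0$queries), unname(src),
               ignore_attr = TRUE)
  f1 <- simulateFamily(pan, rate = 0.1, nQueries = 10, seed = 5)
  f1b <- simulateFamily(pan, rate = 0.1, nQueries = 10, seed = 5)
  expect_identical(as.character(f1$queries), as.character(f1b$queries))
  expect_error(simulateFamily(pan, rate = 0.6), "0.5")
  expect_setequal(f1$tree$tip.label, names(panelSequences(pan)))
  expect_true(all(f1$tree$edge.length > 0))
})

test_that("sub-seed derivation separates streams and stays in range", {
  s1 <- deriveSeed(17, "promoters")
  s2 <- deriveSeed(17, "membranes")
  expect_true(s1 != s2)
  expect_true(s1 >= 0 && s1 < 2^31)
  expect_identical(deriveSeed(17, "promoters"), s1)
})
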