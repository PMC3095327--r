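test_that("background correction subtracts and clips at zero", {
  expect_equal(correctBackground(500, 100), 400)
  expect_equal(correctBackground(80, 100), 0)
  expect_equal(correctBackground(0, 0), 0)
  expect_error(correctBackground(-1, 0), "non-negative")
})

test_that("presence calls are strictly greater-than", {
  expect_true(presenceCall(c(500, 500), c(110, 110)))
  expect_false(presenceCall(100, 110))
  expect_false(presenceCall(110, c(100, 120)))  # equality is absence
  expect_error(presenceCall(numeric(), 10), "no spots")
  expect_error(presenceCall(10, numeric()), "negative-control")
})

test_that("membrane normalization divides by the mean of reference means", {
  spots <- makeSpots(genes = c(t1 = 200, t2 = 50))
  m <- membraneExperiment(spots)
  norm <- normalizeMembrane(m)
  # reference means: 400, 500, 450, 650 -> factor 500; t1: 200/500 = 0.4
  expect_equal(unique(norm$rel[norm$gene_id == "t1"]), 0.4)
  # mean of normalized reference values is 1 by construction
  refRel <- tapply(norm$rel[norm$gene_id %in% c("actin", "EF1a", "EF1g",
                                                "GAPDH")],
                   norm$gene_id[norm$gene_id %in% c("actin", "EF1a",
                                                    "EF1g", "GAPDH")],
                   mean)
  expect_equal(mean(refRel), 1, tolerance = 1e-12)
})

test_that("genes at or below the negative-control mean become absent zeros", {
  spots <- makeSpots(genes = c(t1 = 200, dim = 100), neg = 100)
  norm <- normalizeMembrane(membraneExperiment(spots))
  expect_false(any(norm$present[norm$gene_id == "dim"]))
  expect_equal(unique(norm$rel[norm$gene_id == "dim"]), 0)
  expect_true(all(norm$present[norm$gene_id == "t1"]))
})

test_that("an absent reference gene is a named error", {
  spots <- makeSpots(refs = c(actin = 400, EF1a = 500, EF1g = 450,
                              GAPDH = 50), neg = 100)
  expect_error(normalizeMembrane(membraneExperiment(spots)), "GAPDH")
})

test_that("normalization is scale invariant per membrane", {
  for (c in c(0.1, 1, 17.3)) {
    n0 <- normalizeMembrane(membraneExperiment(makeSpots()))
    n1 <- normalizeMembrane(membraneExperiment(makeSpots(scale = c)))
    expect_equal(n1$rel, n0$rel, tolerance = 1e-12)
    expect_equal(n1$present, n0$present)
  }
})

test_that("replicates pool across membranes at spot level", {
  agg <- aggregateReplicates(list(rep(0.3, 3), rep(0.5, 3)),
                             present = c(TRUE, TRUE))
  expect_equal(agg$mean, 0.4)
  expect_equal(agg$n, 6)
  flat <- aggregateReplicates(list(rep(0.4, 3), rep(0.4, 3)),
                              present = c(TRUE, TRUE))
  expect_equal(flat$sd, 0)
  expect_warning(single <- aggregateReplicates(list(rep(0.2, 3)), TRUE),
                 "single replicate")
  expect_equal(single$n, 3)
})

test_that("high-expression calls are strict per-condition comparisons", {
  mn <- matrix(c(0.01, 0.02, 0.15), 3, 1,
               dimnames = list(paste0("g", 1:3), "leaf"))
  zero <- matrix(0, 3, 1, dimnames = dimnames(mn))
  p <- expressionProfile(mn, zero, zero + 6, mn > -1)
  high <- callHigh(p)
  expect_equal(as.vector(high), c(FALSE, FALSE, TRUE))
  # all equal -> none flagged
  mne <- matrix(0.05, 3, 1, dimnames = dimnames(mn))
  pe <- expressionProfile(mne, zero, zero + 6, mne > -1)
  expect_false(any(callHigh(pe)))
  # invariant under global rescaling
  p10 <- expressionProfile(mn * 10, zero, zero + 6, mn > -1)
  expect_equal(callHigh(p10), high)
})

test_that("preferential and induced calls follow the fold rule", {
  mn <- matrix(c(0.01, 0.01, 0.10,     # preferential in organ3
                 0.05, 0.05, 0.05),    # flat
               2, 3, byrow = TRUE,
               dimnames = list(c("g1", "g2"), paste0("organ", 1:3)))
  zero <- matrix(0, 2, 3, dimnames = dimnames(mn))
  p <- expressionProfile(mn, zero, zero + 6, mn > -1)
  s <- summarizePreferential(p, fold = 2)
  expect_true(s$preferential["g1", "organ3"])
  expect_false(any(s$preferential["g2", ]))
  expect_false(any(s$preferential["g1", c("organ1", "organ2")]))
  expect_error(summarizePreferential(p, fold = 1), "fold")

  stages <- matrix(c(0.01, 0.03, 0.05, 0.06,
                     0.06, 0.05, 0.03, 0.01,
                     0.05, 0.05, 0.05, 0.05),
                   3, 4, byrow = TRUE,
                   dimnames = list(c("up", "down", "flat"),
                                   paste0("waf", c(2, 10, 11, 13))))
  z <- matrix(0, 3, 4, dimnames = dimnames(stages))
  ps <- expressionProfile(stages, z, z + 6, stages > -1)
  ss <- summarizePreferential(ps, fold = 2,
                              stages = paste0("waf", c(2, 10, 11, 13)))
  expect_true(ss$induced["up"])
  expect_false(ss$induced["down"])
  expect_false(ss$induced["flat"])
})

test_that("most-expressed genes are a subset of the above-mean set", {
  mn <- matrix(c(0.01, 0.02, 0.15, 0.05, 0.05, 0.05), 3, 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  zero <- matrix(0, 3, 2, dimnames = dimnames(mn))
  p <- expressionProfile(mn, zero, zero + 6, mn > -1)
  s <- summarizePreferential(p)
  for (cond in c("a", "b")) {
    above <- rownames(mn)[s$above_mean[, cond]]
    expect_true(all(s$most_expressed[[cond]] %in% above))
  }
  expect_length(s$most_expressed[["b"]], 0)  # flat condition
})

test_that("Northern normalization maps the reference to 1", {
  r <- northernNormalize(c(g1 = 330, GAPDH = 100), "GAPDH")
  expect_equal(unname(r["g1"]), 3.3)
  expect_equal(unname(r["GAPDH"]), 1)
  expect_error(northernNormalize(c(g1 = 330, GAPDH = 0), "GAPDH"), "> 0")
  expect_error(northernNormalize(c(g1 = 330), "GAPDH"), "absent")
})

test_that("the full pipeline recovers a zero-noise truth matrix exactly", {
  set.seed(8)
  truth <- matrix(runif(8 * 3, 0.05, 0.4), 8, 3,
                  dimnames = list(sprintf("g%02d", 1:8),
                                  c("leaf", "stem", "root")))
  truth[2, 1] <- 0
  sim <- simulateMembranes(truth, noiseCV = 0, seed = 4)
  p <- macroarrayProfile(sim$spots)
  mn <- SummarizedExperiment::assay(p, "mean")
  expect_equal(mn[rownames(truth), colnames(truth)], truth,
               tolerance = 1e-12)
  expect_equal(SummarizedExperiment::assay(p, "n")[1, 1], 6)
  high <- callHigh(p)
  truthHigh <- sweep(truth, 2, colMeans(truth), ">")
  expect_equal(high[rownames(truth), colnames(truth)], truthHigh)
})
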