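test_that("RIL recombinant fraction matches closed-form anchors", {
  expect_equal(rilRecombFraction(0), 0)
  # d chosen so that the per-meiosis r is exactly 0.25
  d <- -50 * log(1 - 2 * 0.25)
  expect_equal(rilRecombFraction(d), 1 / 3, tolerance = 1e-12)
  expect_equal(rilRecombFraction(1e6), 0.5)
  expect_true(all(diff(rilRecombFraction(seq(0, 200, by = 5))) > 0))
})

test_that("RIL recombinant fraction agrees with a forward selfing simulation", {
  set.seed(101)
  for (r in c(0.05, 0.25)) {
    d <- -50 * log(1 - 2 * r)
    Rhat <- forwardRilRecomb(r, nLines = 1e5)
    R <- rilRecombFraction(d)
    se <- sqrt(R * (1 - R) / 1e5)
    expect_lt(abs(Rhat - R), 3 * se)
  }
})

test_that("simulateBulks is bit-reproducible under a fixed seed", {
  sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 5e6),
                    markerSpacing = 1e5,
                    qtl = data.frame(chrom = "Chr01", pos = 2.5e6, effect = 0.9),
                    seed = 77L)
  s1 <- simulateBulks(sc)
  s2 <- simulateBulks(sc)
  expect_identical(refDepth(s1$sites), refDepth(s2$sites))
  expect_identical(s1$truth, s2$truth)
})

test_that("a null scenario gives delta centred at zero within sampling noise", {
  # markers 100 cM apart are effectively unlinked, so per-marker deltas are
  # independent draws of pure line-composition + read noise
  sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 10e6),
                    markerSpacing = 1e5, recombRate = 1000, meanDepth = 1e4,
                    depthModel = "fixed", seed = 31L)
  sim <- simulateBulks(sc)
  st <- S4Vectors::mcols(computeSnpStats(sim$sites))
  # 100 unlinked markers, per-marker delta SD ~ sqrt(2 * 0.25 / 20) = 0.16
  expect_lt(abs(mean(st$delta)), 4 * 0.16 / sqrt(100))
  # at huge depth, observed indices track the true bulk frequencies
  expect_lt(max(abs(st$indexA - sim$truth$freqHigh)), 0.02)
})

test_that("complete selection drives delta at the QTL towards 1 minus residual heterozygosity", {
  # E[delta at QTL] = 1 - residual heterozygosity = 1 - (1/2)^4 ~ 0.94;
  # average over replicates to separate the expectation from line-sampling
  # noise (SD ~ 0.04 per replicate)
  deltas <- vapply(1:10, function(s) {
    sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 5e6),
                      markerSpacing = 5e4,
                      qtl = data.frame(chrom = "Chr01", pos = 2.5e6, effect = 1),
                      meanDepth = 1e4, depthModel = "fixed",
                      seed = 13L + s)
    sim <- simulateBulks(sc)
    st <- S4Vectors::mcols(computeSnpStats(sim$sites))
    st$delta[which(sim$truth$isCausal)]
  }, numeric(1))
  expect_gte(mean(deltas), 0.9)
})

test_that("empirical bulk frequencies converge to the recorded truth at extreme depth", {
  sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 2e6),
                    markerSpacing = 1e5,
                    qtl = data.frame(chrom = "Chr01", pos = 1e6, effect = 1),
                    meanDepth = 1e5, depthModel = "fixed", seed = 7L)
  sim <- simulateBulks(sc)
  st <- S4Vectors::mcols(computeSnpStats(sim$sites))
  expect_lt(max(abs(st$indexA - sim$truth$freqHigh)), 0.01)
  expect_lt(max(abs(st$indexB - sim$truth$freqLow)), 0.01)
})

test_that("a QTL off the marker grid is inserted as its own marker; bad positions are fatal", {
  sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 1e6),
                    markerSpacing = 1e5,
                    qtl = data.frame(chrom = "Chr01", pos = 123456, effect = 1),
                    seed = 2L)
  sim <- simulateBulks(sc)
  expect_true(123456 %in% BiocGenerics::start(sim$sites))
  expect_error(simScenario(
    chromosomes = data.frame(name = "Chr01", length = 1e6),
    qtl = data.frame(chrom = "Chr01", pos = 2e6, effect = 1)),
    "outside")
  expect_error(simScenario(
    chromosomes = data.frame(name = "Chr01", length = 1e6),
    qtl = data.frame(chrom = "Chr02", pos = 1e5, effect = 1)),
    "not in scenario")
})

test_that("power analysis returns an empty table for zero reps and one row per scenario x statistic", {
  expect_equal(nrow(powerAnalysis(list(), nReps = 0L)), 0)
  sc1 <- simScenario(chromosomes = data.frame(name = "Chr01", length = 4e6),
                     markerSpacing = 1e5,
                     qtl = data.frame(chrom = "Chr01", pos = 2e6, effect = 1))
  sc0 <- simScenario(chromosomes = data.frame(name = "Chr01", length = 4e6),
                     markerSpacing = 1e5)
  cfg <- scanConfig(nPermutations = 30L, seed = 1)
  tab <- powerAnalysis(list(sc1, sc0), cfg, nReps = 2L, seed = 5)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$statistic), c("delta", "gprime", "ed4"))
  # QTL scenario reports coverage, null scenario reports a FP window rate
  expect_true(all(is.finite(tab$coverage[tab$scenario == 1])))
  expect_true(all(is.finite(tab$fpWindowRate[tab$scenario == 2])))
})
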