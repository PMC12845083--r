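test_that("tricube weight matches closed forms and kernel support", {
  expect_equal(tricubeWeight(0, 5e5), 1)
  expect_equal(tricubeWeight(5e5, 5e5), 0)
  expect_equal(tricubeWeight(2.5e5, 5e5), 0.669921875)
  expect_equal(tricubeWeight(-2.5e5, 5e5), 0.669921875)
  expect_equal(tricubeWeight(6e5, 5e5), 0)
})

test_that("G-prime smoothing: single SNP keeps its G, constant G stays constant", {
  x1 <- BulkSnpSet("Chr01", 100, "A", "G", 2, 8, 8, 2)
  s1 <- computeSnpStats(x1)
  expect_equal(gprimeSmooth(s1, 5e5), S4Vectors::mcols(s1)$g)
  n <- 20
  x2 <- BulkSnpSet("Chr01", seq(1e5, 2e6, length.out = n), "A", "G",
                   adRefA = rep(4, n), adAltA = rep(16, n),
                   adRefB = rep(16, n), adAltB = rep(4, n))
  s2 <- computeSnpStats(x2)
  g0 <- S4Vectors::mcols(s2)$g[1]
  expect_equal(gprimeSmooth(s2, 5e5), rep(g0, n))
})

test_that("G-prime smoothing equals the hand-computed weighted mean on a 3-SNP chromosome", {
  x <- BulkSnpSet("Chr01", c(1, 1e5, 5e5) + 1, "A", "G",
                  adRefA = c(10, 10, 2), adAltA = c(10, 12, 18),
                  adRefB = c(10, 12, 18), adAltB = c(10, 10, 2))
  s <- computeSnpStats(x)
  g <- S4Vectors::mcols(s)$g
  h <- 5e5
  # evaluated at the middle SNP: neighbours at offsets 1e5-1... use exact positions
  pos <- BiocGenerics::start(s)
  w <- tricubeWeight(pos - pos[2], h)
  expect_equal(gprimeSmooth(s, h)[2], sum(w * g) / sum(w))
})

test_that("G-prime smoothing equals the naive O(n^2) oracle on a random chromosome", {
  set.seed(19)
  n <- 200
  pos <- sort(sample.int(5e6, n))
  x <- BulkSnpSet("Chr01", pos, "A", "G",
                  adRefA = rpois(n, 15), adAltA = rpois(n, 15),
                  adRefB = rpois(n, 15), adAltB = rpois(n, 15))
  s <- computeSnpStats(x)
  g <- S4Vectors::mcols(s)$g
  expect_equal(gprimeSmooth(s, 4e5), naiveTricube(pos, g, 4e5),
               tolerance = 1e-12)
})

test_that("window scan averages SNP statistics with half-open membership", {
  x <- BulkSnpSet("Chr01", c(1, 999999), "A", "G",
                  adRefA = c(8, 4), adAltA = c(2, 6),
                  adRefB = c(10, 10), adAltB = c(0, 0),
                  seqlengths = c(Chr01 = 1.2e6))
  s <- computeSnpStats(x)
  w <- windowScan(s, scanConfig())
  w0 <- w[BiocGenerics::start(w) == 1]
  # |delta| mean of 0.2 and 0.6 (unpolarized scan averages |Delta|)
  expect_equal(S4Vectors::mcols(w0)$meanDelta, 0.4)
  expect_equal(S4Vectors::mcols(w0)$nSnps, 2L)
})

test_that("windows without SNPs are omitted and the 1 Mb boundary site is assigned half-open", {
  x <- BulkSnpSet("Chr01", c(1e6, 1000001, 5e6), "A", "G",
                  adRefA = c(5, 5, 5), adAltA = c(5, 5, 5),
                  adRefB = c(5, 5, 5), adAltB = c(5, 5, 5),
                  seqlengths = c(Chr01 = 6e6))
  s <- computeSnpStats(x)
  w <- windowScan(s, scanConfig())
  # pos 1e6 has pos-1 = 999999 < 1e6: inside window [0, 1e6);
  # pos 1000001 has pos-1 = 1e6: excluded from it
  w0 <- w[BiocGenerics::start(w) == 1]
  expect_equal(S4Vectors::mcols(w0)$nSnps, 1L)
  # windows covering only the empty 2-4 Mb gap do not appear
  starts <- BiocGenerics::start(w) - 1
  gapOnly <- starts >= 1.1e6 & starts <= 3.9e6
  expect_false(any(gapOnly))
})

test_that("degenerate pair-swap null: identical depth pairs give a zero delta threshold", {
  n <- 100
  x <- BulkSnpSet("Chr01", seq(1e4, 1e6, length.out = n), "A", "G",
                  adRefA = rep(12, n), adAltA = rep(18, n),
                  adRefB = rep(12, n), adAltB = rep(18, n),
                  seqlengths = c(Chr01 = 1.5e6))
  cfg <- scanConfig(nPermutations = 50L, seed = 5, permScheme = "pairSwap")
  th <- permutationThresholds(x, cfg)
  expect_equal(thresholdFor(th, "delta", 0.95), 0)
  expect_equal(thresholdFor(th, "delta", 0.99), 0)
})

test_that("thresholds are monotone in level and bit-reproducible under a fixed seed", {
  set.seed(31)
  x <- simulateNullBulks(300, 30, spacing = 1e4)
  cfg <- scanConfig(nPermutations = 100L, seed = 17)
  th1 <- permutationThresholds(x, cfg)
  th2 <- permutationThresholds(x, cfg)
  expect_identical(th1@thresholds, th2@thresholds)
  for (s in c("delta", "gprime", "ed4"))
    expect_gte(thresholdFor(th1, s, 0.99), thresholdFor(th1, s, 0.95))
  cfg2 <- scanConfig(nPermutations = 100L, seed = 18)
  th3 <- permutationThresholds(x, cfg2)
  expect_false(identical(th1@thresholds, th3@thresholds))
})

test_that("per-chromosome pooling produces one threshold per chromosome", {
  set.seed(9)
  nA <- 150; nB <- 150
  x <- BulkSnpSet(rep(c("Chr01", "Chr02"), c(nA, nB)),
                  c(seq(1e4, 1.5e6, length.out = nA),
                    seq(1e4, 1.5e6, length.out = nB)), "A", "G",
                  adRefA = rpois(nA + nB, 15), adAltA = rpois(nA + nB, 15),
                  adRefB = rpois(nA + nB, 15), adAltB = rpois(nA + nB, 15),
                  seqlengths = c(Chr01 = 1.6e6, Chr02 = 1.6e6))
  cfg <- scanConfig(nPermutations = 50L, seed = 2, pool = "chromosome")
  th <- permutationThresholds(x, cfg)
  expect_setequal(names(th@thresholds), c("Chr01", "Chr02"))
  expect_true(is.finite(thresholdFor(th, "gprime", 0.95, chrom = "Chr02")))
})

test_that("interval calling merges runs of significant windows and reports the peak", {
  # hand-built windows: 1 Mb windows stepping 100 kb along one chromosome
  # non-overlapping 100 kb windows (width = step) so that merge gaps are visible
  mkWindows <- function(vals) {
    n <- length(vals)
    gr <- GenomicRanges::GRanges("Chr01",
      IRanges::IRanges(start = (seq_len(n) - 1) * 1e5 + 1, width = 1e5))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      nSnps = 10L, meanDelta = vals, meanG = 1, gprime = 1, meanEd4 = 0.1)
    gr
  }
  th <- methods::new("ThresholdSet",
                     thresholds = list(genome = matrix(0.5, 1, 1,
                       dimnames = list("delta", "0.95"))),
                     levels = 0.95, seed = 1L, nPermutations = 1L,
                     permScheme = "reads", pool = "genome")
  # none significant
  w <- mkWindows(rep(0.1, 10))
  expect_length(callIntervals(w, th, "delta", 0.95, step = 1e5), 0)
  # five consecutive significant windows -> one interval spanning them
  vals <- c(0.1, 0.6, 0.7, 0.9, 0.7, 0.6, 0.1, 0.1, 0.1, 0.1)
  iv <- callIntervals(mkWindows(vals), th, "delta", 0.95, step = 1e5)
  expect_length(iv, 1)
  expect_equal(BiocGenerics::start(iv), 1e5 + 1)
  expect_equal(BiocGenerics::end(iv), 6e5)
  expect_equal(S4Vectors::mcols(iv)$peakValue, 0.9)
  expect_true(BiocGenerics::start(iv) <= S4Vectors::mcols(iv)$peakPos &&
              S4Vectors::mcols(iv)$peakPos <= BiocGenerics::end(iv))
  # two runs separated by three non-significant windows -> two intervals
  vals2 <- c(0.6, 0.6, 0.1, 0.1, 0.1, 0.6, 0.6, 0.1, 0.1, 0.1)
  iv2 <- callIntervals(mkWindows(vals2), th, "delta", 0.95, step = 1e5)
  expect_length(iv2, 2)
  # unknown statistic is fatal
  expect_error(callIntervals(mkWindows(vals), th, "zscore", 0.95, step = 1e5),
               "unknown statistic")
})

test_that("reservoir accumulation approximates exact quantiles above the cap", {
  set.seed(23)
  x <- simulateNullBulks(400, 30, spacing = 1e4)
  cfgExact <- scanConfig(nPermutations = 200L, seed = 4)
  cfgRes <- scanConfig(nPermutations = 200L, seed = 4, maxNullValues = 2000)
  thE <- permutationThresholds(x, cfgExact)
  thR <- permutationThresholds(x, cfgRes)
  for (s in c("delta", "gprime", "ed4")) {
    e <- thresholdFor(thE, s, 0.95)
    r <- thresholdFor(thR, s, 0.95)
    expect_lt(abs(r - e) / e, 0.15)
  }
})
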