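test_that("header-only VCF ingests to an empty set with a zero report", {
  path <- writeTestVcf(character(0))
  x <- readBulkVcf(path, "bulkA", "bulkB")
  expect_s4_class(x, "BulkSnpSet")
  expect_length(x, 0)
  expect_equal(ingestReport(x)$nTotal, 0L)
})

test_that("biallelic SNPs are kept; multiallelic sites, indels and missing AD are counted out", {
  path <- writeTestVcf(c(
    "Chr01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:12,8\t0/1:7,13",
    "Chr01\t200\t.\tC\tG,T\t50\tPASS\t.\tGT:AD\t0/1:5,5,2\t0/1:6,4,1",
    "Chr01\t300\t.\tAT\tA\t50\tPASS\t.\tGT:AD\t0/1:5,5\t0/1:6,4",
    "Chr01\t400\t.\tG\tC\t50\tPASS\t.\tGT:AD\t.\t0/1:6,4"))
  x <- readBulkVcf(path, "bulkA", "bulkB")
  rep <- ingestReport(x)
  expect_length(x, 1)
  expect_equal(unname(refDepth(x)[1, ]), c(12L, 7L))
  expect_equal(unname(altDepth(x)[1, ]), c(8L, 13L))
  expect_equal(rep$nMultiallelicDropped, 1L)
  expect_equal(rep$nIndelDropped, 1L)
  expect_equal(rep$nMissingAdDropped, 1L)
  expect_equal(rep$nRetained + rep$nMultiallelicDropped + rep$nIndelDropped +
                 rep$nMissingAdDropped + rep$nDepthFiltered, rep$nTotal)
})

test_that("keepIndels readmits indel records", {
  path <- writeTestVcf(c(
    "Chr01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:12,8\t0/1:7,13",
    "Chr01\t300\t.\tAT\tA\t50\tPASS\t.\tGT:AD\t0/1:5,5\t0/1:6,4"))
  x <- readBulkVcf(path, "bulkA", "bulkB", keepIndels = TRUE)
  expect_length(x, 2)
  expect_equal(ingestReport(x)$nIndelDropped, 0L)
})

test_that("a missing sample name is a fatal configuration error", {
  path <- writeTestVcf("Chr01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:12,8\t0/1:7,13")
  expect_error(readBulkVcf(path, "bulkA", "nope"), "nope")
})

test_that("depth filter keeps sites covered >= minDepth in both bulks, strictly discarding < 10", {
  x <- BulkSnpSet("Chr01", c(100, 200, 300, 400), "A", "G",
                  adRefA = c(4, 5, 25, 6), adAltA = c(5, 5, 25, 6),
                  adRefB = c(15, 5, 4, 6), adAltB = c(15, 5, 4, 6))
  # per-bulk totals: (9,30), (10,10), (50,8), (12,12)
  f <- filterDepth(x, 10)
  expect_length(f, 2)
  expect_equal(BiocGenerics::start(f), c(200L, 400L))  # order preserved
  expect_equal(ingestReport(f)$nDepthFiltered, 2L)
  # boundary: totals of exactly 10 in both bulks are retained
  expect_true(200L %in% BiocGenerics::start(f))
  # idempotent
  f2 <- filterDepth(f, 10)
  expect_equal(BiocGenerics::start(f2), BiocGenerics::start(f))
  expect_equal(ingestReport(f2)$nDepthFiltered, 2L)
  # empty input -> empty output
  expect_length(filterDepth(x[integer(0), ], 10), 0)
})

test_that("polarization orients alt to the high-parent allele and flags unpolarizable sites", {
  mk <- function() BulkSnpSet("Chr01", c(100, 200, 300), c("A", "C", "G"),
                              c("G", "T", "A"),
                              adRefA = c(2, 3, 4), adAltA = c(8, 7, 6),
                              adRefB = c(9, 8, 7), adAltB = c(1, 2, 3))
  x <- mk()
  # site 1: high parent hom alt -> unchanged; site 2: high hom ref -> swapped;
  # site 3: high het -> unpolarizable, untouched
  p <- polarizeSites(x, gtHigh = c(2L, 0L, 1L), gtLow = c(0L, 2L, 0L))
  expect_equal(isPolarized(p), c(TRUE, TRUE, NA))
  expect_equal(unname(refDepth(p)[1, ]), c(2L, 9L))
  expect_equal(unname(refDepth(p)[2, ]), c(7L, 2L))    # pair swapped
  expect_equal(unname(altDepth(p)[2, ]), c(3L, 8L))
  rd <- SummarizedExperiment::rowData(p)
  expect_equal(rd$ref[2], "T")                         # labels swapped
  expect_equal(rd$alt[2], "C")
  expect_equal(unname(refDepth(p)[3, ]), c(4L, 7L))    # untouched
  # missing parent call is unpolarizable too
  p2 <- polarizeSites(mk(), gtHigh = c(NA, 2L, 2L), gtLow = c(0L, 0L, 0L))
  expect_true(is.na(isPolarized(p2)[1]))
})

test_that("polarizing twice with updated dosages is a no-op; double swap restores orientation", {
  x <- BulkSnpSet("Chr01", c(100, 200), c("A", "C"), c("G", "T"),
                  adRefA = c(2, 3), adAltA = c(8, 7),
                  adRefB = c(9, 8), adAltB = c(1, 2))
  gtHigh <- c(0L, 2L); gtLow <- c(2L, 0L)
  p1 <- polarizeSites(x, gtHigh, gtLow)
  # after polarization the high parent is hom-alt everywhere by construction
  p2 <- polarizeSites(p1, c(2L, 2L), c(0L, 0L))
  expect_identical(refDepth(p2), refDepth(p1))
  expect_identical(SummarizedExperiment::rowData(p2)$alt,
                   SummarizedExperiment::rowData(p1)$alt)
  # the raw orientation swap is an involution
  s2 <- BSAscan:::.swapOrientation(BSAscan:::.swapOrientation(x, c(TRUE, TRUE)),
                                   c(TRUE, TRUE))
  expect_identical(refDepth(s2), refDepth(x))
  expect_identical(SummarizedExperiment::rowData(s2)$ref,
                   SummarizedExperiment::rowData(x)$ref)
})

test_that("parent-polarized ingestion from VCF swaps depths and flags het parents", {
  path <- writeTestVcf(c(
    "Chr01\t100\t.\tA\tG\t50\tPASS\t.\tGT:AD\t0/1:12,8\t0/1:7,13\t1/1:0,9\t0/0:11,0",
    "Chr01\t200\t.\tC\tT\t50\tPASS\t.\tGT:AD\t0/1:5,5\t0/1:6,4\t0/0:9,0\t1/1:0,8",
    "Chr01\t300\t.\tG\tA\t50\tPASS\t.\tGT:AD\t0/1:5,5\t0/1:6,4\t0/1:4,4\t0/0:8,0"),
    samples = c("bulkA", "bulkB", "pHigh", "pLow"))
  x <- readBulkVcf(path, "bulkA", "bulkB", parentHigh = "pHigh", parentLow = "pLow")
  expect_equal(isPolarized(x), c(TRUE, TRUE, NA))
  expect_equal(unname(altDepth(x)[2, ]), c(5L, 6L))  # swapped at site 2
  expect_equal(SummarizedExperiment::rowData(x)$alt[2], "C")
})

test_that("write/read round-trip recovers every site and depth exactly", {
  set.seed(42)
  n <- 100
  pos <- sort(sample.int(1e6, n))
  x <- BulkSnpSet(chrom = "Chr01", pos = pos,
                  ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
                  alt = "N",
                  adRefA = rpois(n, 20), adAltA = rpois(n, 20),
                  adRefB = rpois(n, 20), adAltB = rpois(n, 20),
                  seqlengths = c(Chr01 = 2e6))
  # make alt differ from ref
  rd <- SummarizedExperiment::rowData(x)
  rd$alt <- ifelse(rd$ref == "A", "G", "A")
  SummarizedExperiment::rowData(x) <- rd
  path <- tempfile(fileext = ".vcf")
  writeBulkVcf(x, path)
  y <- readBulkVcf(path, "bulkA", "bulkB")
  expect_equal(BiocGenerics::start(y), BiocGenerics::start(x))
  expect_equal(refDepth(y), refDepth(x))
  expect_equal(altDepth(y), altDepth(x))
  expect_equal(SummarizedExperiment::rowData(y)$ref,
               SummarizedExperiment::rowData(x)$ref)
})

test_that("empty write round-trips and contract violations are fatal", {
  x <- BulkSnpSet(character(), integer(), character(), character(),
                  integer(), integer(), integer(), integer())
  path <- tempfile(fileext = ".vcf")
  writeBulkVcf(x, path, contigLengths = c(Chr01 = 1e6))
  expect_length(readBulkVcf(path, "bulkA", "bulkB"), 0)
  # position beyond contig length
  bad <- BulkSnpSet("Chr01", 2e6, "A", "G", 5, 5, 5, 5)
  expect_error(writeBulkVcf(bad, tempfile(), contigLengths = c(Chr01 = 1e6)),
               "beyond contig")
})

test_that("site table export carries all depth fields", {
  x <- BulkSnpSet("Chr01", c(100, 200), "A", "G",
                  adRefA = c(1, 2), adAltA = c(3, 4),
                  adRefB = c(5, 6), adAltB = c(7, 8))
  path <- tempfile(fileext = ".tsv")
  exportSiteTable(x, path)
  tab <- read.delim(path)
  expect_equal(tab$ad_a_alt, c(3L, 4L))
  expect_equal(tab$ad_b_ref, c(5L, 6L))
  expect_equal(tab$polarized, c(FALSE, FALSE))
})
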