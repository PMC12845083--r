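#' @include AllGenerics.R
NULL

#' BulkSnpSet: polarized biallelic sites with per-bulk allelic depths
#'
#' `BulkSnpSet` extends [SummarizedExperiment::RangedSummarizedExperiment].
#' Rows are biallelic variant sites (a `GRanges` with `ref`/`alt` alleles and
#' a `polarized` flag in `rowData`), columns are the two phenotype bulks
#' (column 1 = bulk A, column 2 = bulk B). Two integer assays, `adRef` and
#' `adAlt`, hold the per-bulk reference- and alternate-allele read depths
#' that every downstream BSA statistic consumes.
#'
#' The `polarized` flag per site is `TRUE` when the `alt` allele is the
#' allele carried (homozygously) by the designated high-trait parent, `FALSE`
#' when no parental information was used (the VCF ALT defines orientation),
#' and `NA` when polarization was attempted but the site is unpolarizable
#' (heterozygous or missing parent call). Unpolarizable sites are excluded
#' from signed Delta-SNP-index scans but retained for |Delta|, G and ED.
#'
#' @slot ingestReport list of ingestion/filtering counters, see
#'   [ingestReport()].
#'
#' @seealso [readBulkVcf()], [filterDepth()], [computeSnpStats()]
#' @export
setClass("BulkSnpSet", contains = "RangedSummarizedExperiment")

setValidity("BulkSnpSet", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("adRef", "adAlt") %in% an))
    msg <- c(msg, "assays 'adRef' and 'adAlt' are required")
  else {
    for (a in c("adRef", "adAlt")) {
      m <- SummarizedExperiment::assay(object, a)
      if (ncol(m) != 2L)
        msg <- c(msg, sprintf("assay '%s' must have exactly 2 bulk columns", a))
      if (anyNA(m) || any(m < 0))
        msg <- c(msg, sprintf("assay '%s' must be non-negative and NA-free", a))
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt", "polarized") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'ref', 'alt' and 'polarized'")
  if (length(object) && any(BiocGenerics::start(object) < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a BulkSnpSet from site vectors
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based positions (bp).
#' @param ref,alt allele strings (single bases for SNPs).
#' @param adRefA,adAltA,adRefB,adAltB non-negative integer read depths of the
#'   reference/alternate allele in bulk A and bulk B.
#' @param polarized logical (recycled): `TRUE` = alt is the high-parent
#'   allele, `FALSE` = unpolarized, `NA` = unpolarizable.
#' @param bulkNames names for the two bulk columns.
#' @param seqlengths optional named vector of chromosome lengths.
#' @param ingestReport optional list of ingestion counters.
#' @param metadata optional list merged into `metadata()`.
#'
#' @return A [BulkSnpSet-class] object sorted by (chrom, pos).
#' @examples
#' x <- BulkSnpSet("Chr01", c(100, 200), ref = "A", alt = "G",
#'                 adRefA = c(12, 5), adAltA = c(8, 5),
#'                 adRefB = c(7, 6), adAltB = c(13, 4))
#' totalDepth(x)
#' @export
BulkSnpSet <- function(chrom, pos, ref, alt,
                       adRefA, adAltA, adRefB, adAltB,
                       polarized = FALSE,
                       bulkNames = c("bulkA", "bulkB"),
                       seqlengths = NULL,
                       ingestReport = NULL,
                       metadata = list()) {
  n <- length(pos)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(as.character(chrom), length.out = n),
    ranges = IRanges::IRanges(start = as.integer(pos),
                              width = nchar(rep(as.character(ref), length.out = n))))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    ref = rep(as.character(ref), length.out = n),
    alt = rep(as.character(alt), length.out = n),
    polarized = rep(as.logical(polarized), length.out = n))
  adRef <- cbind(as.integer(adRefA), as.integer(adRefB))
  adAlt <- cbind(as.integer(adAltA), as.integer(adAltB))
  colnames(adRef) <- colnames(adAlt) <- bulkNames
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(adRef = adRef, adAlt = adAlt),
    rowRanges = gr,
    colData = S4Vectors::DataFrame(bulk = c("A", "B"), row.names = bulkNames))
  obj <- methods::new("BulkSnpSet", se)
  if (is.null(ingestReport))
    ingestReport <- newIngestReport(nTotal = n, nRetained = n)
  S4Vectors::metadata(obj) <- c(list(ingestReport = ingestReport), metadata)
  sortSites(obj)
}

## empty ingestion report; counters are filled by readBulkVcf()/filterDepth()
newIngestReport <- function(nTotal = 0L, nMultiallelicDropped = 0L,
                            nIndelDropped = 0L, nMissingAdDropped = 0L,
                            nDepthFiltered = 0L, nRetained = 0L) {
  list(nTotal = as.integer(nTotal),
       nMultiallelicDropped = as.integer(nMultiallelicDropped),
       nIndelDropped = as.integer(nIndelDropped),
       nMissingAdDropped = as.integer(nMissingAdDropped),
       nDepthFiltered = as.integer(nDepthFiltered),
       nRetained = as.integer(nRetained))
}

sortSites <- function(x) {
  o <- BiocGenerics::order(SummarizedExperiment::rowRanges(x))
  x[o, ]
}

#' Scan configuration
#'
#' Holds the tunable parameters of the sliding-window/G-prime genome scan and
#' of the permutation threshold machinery.
#'
#' @slot windowSize sliding window width in bp (default 1 Mb).
#' @slot stepSize window step in bp (default 100 kb).
#' @slot tricubeHalfwidth tricube kernel half-width in bp used for G-prime
#'   (default `windowSize / 2`, so the kernel footprint matches the window).
#' @slot nPermutations number of Monte-Carlo bulk-label permutations.
#' @slot levels quantile levels for the empirical thresholds.
#' @slot seed RNG seed used by [permutationThresholds()].
#' @slot minSnpsPerWindow windows with fewer SNPs are not emitted.
#' @slot permScheme `"reads"` (re-partition each site's pooled reads between
#'   the bulks, preserving per-bulk depth) or `"pairSwap"` (swap the two bulk
#'   depth pairs with probability 1/2; leaves G and ED unchanged, only
#'   meaningful for Delta).
#' @slot pool `"genome"` (one genome-wide threshold per statistic) or
#'   `"chromosome"`.
#' @slot maxNullValues cap on materialized null values per statistic; above
#'   it a fixed-size uniform reservoir subsample feeds the quantiles.
#' @export
setClass("ScanConfig",
         representation(windowSize = "numeric",
                        stepSize = "numeric",
                        tricubeHalfwidth = "numeric",
                        nPermutations = "integer",
                        levels = "numeric",
                        seed = "integer",
                        minSnpsPerWindow = "integer",
                        permScheme = "character",
                        pool = "character",
                        maxNullValues = "numeric"))

setValidity("ScanConfig", function(object) {
  msg <- NULL
  if (object@stepSize > object@windowSize)
    msg <- c(msg, "stepSize must be <= windowSize")
  if (object@windowSize <= 0 || object@stepSize <= 0)
    msg <- c(msg, "windowSize and stepSize must be positive")
  if (object@tricubeHalfwidth <= 0)
    msg <- c(msg, "tricubeHalfwidth must be positive")
  if (object@nPermutations < 1L)
    msg <- c(msg, "nPermutations must be >= 1")
  if (any(object@levels <= 0 | object@levels >= 1))
    msg <- c(msg, "levels must lie strictly in (0, 1)")
  if (!object@permScheme %in% c("reads", "pairSwap"))
    msg <- c(msg, "permScheme must be 'reads' or 'pairSwap'")
  if (!object@pool %in% c("genome", "chromosome"))
    msg <- c(msg, "pool must be 'genome' or 'chromosome'")
  if (object@minSnpsPerWindow < 1L)
    msg <- c(msg, "minSnpsPerWindow must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @param windowSize,stepSize,tricubeHalfwidth,nPermutations,levels,seed,minSnpsPerWindow,permScheme,pool,maxNullValues
#'   see slot documentation in [ScanConfig-class].
#' @return `scanConfig()` returns a validated `ScanConfig`.
#' @examples
#' scanConfig(nPermutations = 500, seed = 7)
#' @rdname ScanConfig-class
#' @export
scanConfig <- function(windowSize = 1e6,
                       stepSize = 1e5,
                       tricubeHalfwidth = windowSize / 2,
                       nPermutations = 100000L,
                       levels = c(0.95, 0.99),
                       seed = 1L,
                       minSnpsPerWindow = 1L,
                       permScheme = c("reads", "pairSwap"),
                       pool = c("genome", "chromosome"),
                       maxNullValues = 1e7) {
  methods::new("ScanConfig",
               windowSize = windowSize,
               stepSize = stepSize,
               tricubeHalfwidth = tricubeHalfwidth,
               nPermutations = as.integer(nPermutations),
               levels = sort(levels),
               seed = as.integer(seed),
               minSnpsPerWindow = as.integer(minSnpsPerWindow),
               permScheme = match.arg(permScheme),
               pool = match.arg(pool),
               maxNullValues = maxNullValues)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig\n")
  cat(sprintf("  window %.0f bp, step %.0f bp, tricube halfwidth %.0f bp\n",
              object@windowSize, object@stepSize, object@tricubeHalfwidth))
  cat(sprintf("  %d permutations (%s scheme, %s pooling), levels %s, seed %d\n",
              object@nPermutations, object@permScheme, object@pool,
              paste(object@levels, collapse = "/"), object@seed))
})

#' Empirical significance thresholds from bulk-label permutation
#'
#' One threshold per (statistic, level) pair and per pooling unit ("genome",
#' or one per chromosome when the scan pools per chromosome), computed as
#' quantiles of the pooled null smoothed values.
#'
#' @slot thresholds named list of numeric matrices (rows = statistics,
#'   columns = levels), one per pooling unit.
#' @slot levels quantile levels.
#' @slot seed,nPermutations,permScheme,pool provenance of the null.
#' @seealso [permutationThresholds()], [thresholdFor()]
#' @export
setClass("ThresholdSet",
         representation(thresholds = "list",
                        levels = "numeric",
                        seed = "integer",
                        nPermutations = "integer",
                        permScheme = "character",
                        pool = "character"))

setValidity("ThresholdSet", function(object) {
  msg <- NULL
  for (m in object@thresholds) {
    if (!is.matrix(m))
      msg <- c(msg, "thresholds must be matrices")
    else if (ncol(m) > 1L) {
      mono <- apply(m, 1L, function(r) all(diff(r[!is.na(r)]) >= 0))
      if (!all(mono))
        msg <- c(msg, "thresholds must be non-decreasing in level")
    }
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ThresholdSet", function(object) {
  cat(sprintf("ThresholdSet (%d permutations, %s scheme, %s pooling, seed %d)\n",
              object@nPermutations, object@permScheme, object@pool, object@seed))
  for (nm in names(object@thresholds)) {
    cat(" ", nm, "\n")
    print(round(object@thresholds[[nm]], 4))
  }
})

#' @describeIn ThresholdSet-class look up the threshold for one statistic at
#'   one level (and one chromosome under per-chromosome pooling).
#' @param x a `ThresholdSet`.
#' @param statistic one of `"delta"`, `"gprime"`, `"ed4"`.
#' @param level a confidence level present in the set, e.g. `0.95`.
#' @param chrom pooling unit; `"genome"` (default) or a chromosome name.
#' @export
setMethod("thresholdFor", "ThresholdSet",
  function(x, statistic, level, chrom = "genome") {
    if (x@pool == "genome") chrom <- "genome"
    m <- x@thresholds[[chrom]]
    if (is.null(m))
      stop("no thresholds for pooling unit '", chrom, "'")
    if (!statistic %in% rownames(m))
      stop("unknown statistic '", statistic, "'")
    j <- match(as.character(level), colnames(m))
    if (is.na(j))
      stop("level ", level, " not present in ThresholdSet")
    m[statistic, j]
  })

#' Simulation scenario for RIL bulk sequencing
#'
#' Describes a recombinant-inbred-line (RIL) bulked-segregant design: marker
#' grid, genetic map, causal loci with their selection strength, bulk
#' composition, and the read-sampling model. See [simulateBulks()].
#'
#' @slot chromosomes data.frame with columns `name`, `length` (bp).
#' @slot markerSpacing distance between adjacent markers (bp).
#' @slot recombRate genetic map density in cM/Mb (Haldane, no interference).
#' @slot qtl data.frame with columns `chrom`, `pos` (bp) and `effect`, the
#'   probability that a line selected into the high bulk carries the
#'   high-trait allele at the QTL (0.5 = no selection, 1 = complete
#'   selection). At most one QTL per chromosome.
#' @slot nLinesPerBulk lines pooled per bulk.
#' @slot generation selfing generation of the lines (F5 by default); residual
#'   per-locus heterozygosity is `(1/2)^(generation - 1)`.
#' @slot meanDepth expected read depth per site per bulk.
#' @slot depthModel `"poisson"` or `"fixed"`.
#' @slot seed RNG seed (`NA` = leave the RNG state alone).
#' @export
setClass("SimScenario",
         representation(chromosomes = "data.frame",
                        markerSpacing = "numeric",
                        recombRate = "numeric",
                        qtl = "data.frame",
                        nLinesPerBulk = "integer",
                        generation = "integer",
                        meanDepth = "numeric",
                        depthModel = "character",
                        seed = "integer"))

setValidity("SimScenario", function(object) {
  msg <- NULL
  if (!all(c("name", "length") %in% colnames(object@chromosomes)))
    msg <- c(msg, "chromosomes needs columns 'name' and 'length'")
  if (object@markerSpacing <= 0)
    msg <- c(msg, "markerSpacing must be positive")
  if (object@meanDepth <= 0)
    msg <- c(msg, "meanDepth must be positive")
  if (object@recombRate < 0)
    msg <- c(msg, "recombRate must be non-negative")
  if (nrow(object@qtl)) {
    if (!all(c("chrom", "pos", "effect") %in% colnames(object@qtl)))
      msg <- c(msg, "qtl needs columns 'chrom', 'pos', 'effect'")
    else {
      if (any(object@qtl$effect <= 0.5 | object@qtl$effect > 1))
        msg <- c(msg, "qtl effects must lie in (0.5, 1]")
      i <- match(object@qtl$chrom, object@chromosomes$name)
      if (anyNA(i))
        msg <- c(msg, "qtl chromosome not in scenario chromosomes")
      else if (any(object@qtl$pos < 1 | object@qtl$pos > object@chromosomes$length[i]))
        msg <- c(msg, "qtl position outside its chromosome")
      if (anyDuplicated(object@qtl$chrom))
        msg <- c(msg, "at most one QTL per chromosome is supported")
    }
  }
  if (!object@depthModel %in% c("poisson", "fixed"))
    msg <- c(msg, "depthModel must be 'poisson' or 'fixed'")
  if (object@nLinesPerBulk < 1L)
    msg <- c(msg, "nLinesPerBulk must be >= 1")
  if (object@generation < 2L)
    msg <- c(msg, "generation must be >= 2 (F2 or later)")
  if (is.null(msg)) TRUE else msg
})

#' @param chromosomes,markerSpacing,recombRate,qtl,nLinesPerBulk,generation,meanDepth,depthModel,seed
#'   see slot documentation in [SimScenario-class]. Defaults mirror the
#'   RIL design the scan targets: two bulks of 20 F5 lines each, sequenced
#'   to ~40x per bulk.
#' @return `simScenario()` returns a validated `SimScenario`.
#' @examples
#' sc <- simScenario(qtl = data.frame(chrom = "Chr01", pos = 12.5e6, effect = 1))
#' sc
#' @rdname SimScenario-class
#' @export
simScenario <- function(chromosomes = data.frame(name = "Chr01", length = 25e6),
                        markerSpacing = 25e3,
                        recombRate = 2,
                        qtl = data.frame(chrom = character(), pos = numeric(),
                                         effect = numeric()),
                        nLinesPerBulk = 20L,
                        generation = 5L,
                        meanDepth = 40,
                        depthModel = c("poisson", "fixed"),
                        seed = NA_integer_) {
  methods::new("SimScenario",
               chromosomes = chromosomes,
               markerSpacing = markerSpacing,
               recombRate = recombRate,
               qtl = qtl,
               nLinesPerBulk = as.integer(nLinesPerBulk),
               generation = as.integer(generation),
               meanDepth = meanDepth,
               depthModel = match.arg(depthModel),
               seed = as.integer(seed))
}

setMethod("show", "SimScenario", function(object) {
  cat("SimScenario\n")
  cat(sprintf("  %d chromosome(s), markers every %.0f bp, %.2g cM/Mb\n",
              nrow(object@chromosomes), object@markerSpacing, object@recombRate))
  cat(sprintf("  %d F%d lines per bulk, mean depth %.0fx (%s)\n",
              object@nLinesPerBulk, object@generation, object@meanDepth,
              object@depthModel))
  if (nrow(object@qtl))
    cat(sprintf("  QTL: %s\n",
                paste(sprintf("%s:%.0f (effect %.2f)", object@qtl$chrom,
                              object@qtl$pos, object@qtl$effect),
                      collapse = ", ")))
  else cat("  no QTL (null scenario)\n")
})
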