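#' @include AllGenerics.R AllClasses.R
NULL

#' Per-bulk SNP-index
#'
#' The SNP-index of a bulk at a site is the fraction of its reads carrying
#' the alternate allele, `altDepth / (refDepth + altDepth)`. Sites with zero
#' total depth are undefined (`NA`), never zero.
#'
#' @param refDepth,altDepth non-negative read counts (vectorized).
#' @return numeric vector in `[0, 1]`, `NA` where total depth is zero.
#' @examples
#' snpIndex(c(5, 0, 3), c(5, 12, 9))  # 0.5, 1, 0.75
#' @export
snpIndex <- function(refDepth, altDepth) {
  tot <- refDepth + altDepth
  ifelse(tot > 0, altDepth / tot, NA_real_)
}

#' Delta-SNP-index
#'
#' Difference between the SNP-index of the high-trait bulk and that of the
#' low-trait bulk. Near zero at unlinked loci; approaches +1 near a causal
#' locus when sites are polarized so that `alt` is the high-parent allele.
#'
#' @param indexHigh,indexLow SNP-indices of the high/low bulk.
#' @param absolute return `|Delta|` (for unpolarized scans).
#' @return numeric vector in `[-1, 1]` (or `[0, 1]` when `absolute`).
#' @export
deltaSnpIndex <- function(indexHigh, indexLow, absolute = FALSE) {
  d <- indexHigh - indexLow
  if (absolute) abs(d) else d
}

#' G statistic of the 2x2 allele-by-bulk read-count table
#'
#' Log-likelihood-ratio statistic `G = 2 * sum(n * ln(n / nhat))` over the
#' four cells (bulk x allele), with expected counts `nhat` from the row and
#' column marginals under independence. Cells with observed count 0
#' contribute 0 (`0 * ln(0/x) = 0`), and a zero marginal forces both its
#' observed and expected cells to 0, so zero-margin tables return G = 0.
#'
#' @param aRef,aAlt,bRef,bAlt read counts of the ref/alt allele in bulk A/B
#'   (vectorized).
#' @return numeric vector, `G >= 0`; `NA` for all-zero tables.
#' @examples
#' gStatistic(10, 10, 10, 10)  # identical proportions -> 0
#' gStatistic(20, 5, 5, 20)
#' @export
gStatistic <- function(aRef, aAlt, bRef, bAlt) {
  # doubles throughout: marginal products overflow 32-bit integers at high depth
  aRef <- as.numeric(aRef); aAlt <- as.numeric(aAlt)
  bRef <- as.numeric(bRef); bAlt <- as.numeric(bAlt)
  tot <- aRef + aAlt + bRef + bAlt
  rowA <- aRef + aAlt
  rowB <- bRef + bAlt
  colRef <- aRef + bRef
  colAlt <- aAlt + bAlt
  cell <- function(n, e) ifelse(n > 0, n * log(n / e), 0)
  g <- 2 * (cell(aRef, rowA * colRef / tot) +
            cell(aAlt, rowA * colAlt / tot) +
            cell(bRef, rowB * colRef / tot) +
            cell(bAlt, rowB * colAlt / tot))
  g <- pmax(g, 0)          # guard against negative rounding residue
  g[tot == 0] <- NA_real_
  g
}

#' Euclidean distance statistics between bulk allele frequencies
#'
#' For a biallelic site the Euclidean distance between the two bulks'
#' allele-frequency vectors over both allele axes is
#' `ED = sqrt(2 * (fA - fB)^2) = sqrt(2) * |fA - fB|`, and `ED4 = ED^4`
#' sharpens the signal-to-noise ratio by suppressing small background
#' contrasts.
#'
#' @param freqAAlt,freqBAlt alternate-allele frequencies of bulk A/B.
#' @return data.frame with columns `ed` (in `[0, sqrt(2)]`) and `ed4`
#'   (in `[0, 4]`).
#' @examples
#' euclideanStats(0.8, 0.2)  # ed = sqrt(0.72), ed4 = 0.5184
#' @export
euclideanStats <- function(freqAAlt, freqBAlt) {
  ed <- sqrt(2) * abs(freqAAlt - freqBAlt)
  data.frame(ed = ed, ed4 = ed^4)
}

#' Compute all per-SNP bulk-contrast statistics
#'
#' Populates, for every site, the two bulk SNP-indices, the Delta-SNP-index
#' (high minus low bulk), the G statistic and ED/ED4. Sites where a
#' statistic is undefined (zero depth) carry `NA`, not 0.
#'
#' @param x a depth-filtered [BulkSnpSet-class].
#' @param highBulk which bulk column is the high-trait bulk, `"A"` (default)
#'   or `"B"`.
#' @param lowIndex `"bulk"` (default): Delta is indexHigh minus the other
#'   bulk's index. `"parentMean"`: substitute the mean of the two parents'
#'   SNP-indices for the low index (requires parent depths ingested by
#'   [readBulkVcf()]).
#' @return A `GRanges` with metadata columns `indexA`, `indexB`, `delta`,
#'   `g`, `ed`, `ed4` and `polarized`; `metadata()` records `highBulk`.
#' @examples
#' x <- BulkSnpSet("Chr01", 100, "A", "G", 2, 8, 8, 2)
#' computeSnpStats(x)
#' @export
computeSnpStats <- function(x, highBulk = c("A", "B"),
                            lowIndex = c("bulk", "parentMean")) {
  highBulk <- match.arg(highBulk)
  lowIndex <- match.arg(lowIndex)
  adRef <- unname(refDepth(x))
  adAlt <- unname(altDepth(x))
  indexA <- unname(snpIndex(adRef[, 1L], adAlt[, 1L]))
  indexB <- unname(snpIndex(adRef[, 2L], adAlt[, 2L]))
  indexHigh <- if (highBulk == "A") indexA else indexB
  low <- if (highBulk == "A") indexB else indexA
  if (lowIndex == "parentMean") {
    ph <- S4Vectors::metadata(x)$parentHighDepth
    pl <- S4Vectors::metadata(x)$parentLowDepth
    if (is.null(ph) || is.null(pl))
      stop("parentMean requires parent depths; ingest with parentHigh/parentLow")
    low <- (snpIndex(ph[, 1L], ph[, 2L]) + snpIndex(pl[, 1L], pl[, 2L])) / 2
  }
  gr <- GenomicRanges::granges(SummarizedExperiment::rowRanges(x))
  es <- euclideanStats(indexA, indexB)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    indexA = indexA,
    indexB = indexB,
    delta = unname(deltaSnpIndex(indexHigh, low)),
    g = unname(gStatistic(adRef[, 1L], adAlt[, 1L], adRef[, 2L], adAlt[, 2L])),
    ed = es$ed,
    ed4 = es$ed4,
    polarized = isPolarized(x))
  S4Vectors::metadata(gr) <- list(highBulk = highBulk, lowIndex = lowIndex)
  gr
}

#' Export the per-SNP statistic table as TSV
#'
#' Columns: `chrom`, `pos`, `index_a`, `index_b`, `delta`, `g`, `ed4`;
#' undefined values are written as `.`.
#'
#' @param stats output of [computeSnpStats()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
exportStatTable <- function(stats, path) {
  m <- S4Vectors::mcols(stats)
  fmt <- function(v) ifelse(is.na(v), ".", format(v, digits = 10, trim = TRUE))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(stats)),
    pos = BiocGenerics::start(stats),
    index_a = fmt(m$indexA), index_b = fmt(m$indexB),
    delta = fmt(m$delta), g = fmt(m$g), ed4 = fmt(m$ed4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
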