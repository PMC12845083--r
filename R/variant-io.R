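#' @include AllGenerics.R AllClasses.R
NULL

## per-sample (ref, alt) depth columns from a readVcf AD container, which is
## either a matrix of integer lists (ragged) or a 3-d array (uniform ploidy)
.adColumns <- function(ad, sample) {
  if (is.list(ad)) {
    col <- ad[, sample]
    list(ref = vapply(col, function(v)
           if (length(v) >= 1L) as.integer(v[1L]) else NA_integer_, integer(1)),
         alt = vapply(col, function(v)
           if (length(v) >= 2L) as.integer(v[2L]) else NA_integer_, integer(1)),
         len = lengths(col))
  } else {
    list(ref = as.integer(ad[, sample, 1L]),
         alt = as.integer(ad[, sample, 2L]),
         len = rep.int(dim(ad)[3L], nrow(ad)))
  }
}

## genotype dosage of the ALT allele from a GT string: 0, 1, 2 or NA
.gtDosage <- function(gt) {
  al <- strsplit(unname(gt), "[/|]")
  vapply(al, function(a) {
    if (!length(a) || any(a == ".") || any(!a %in% c("0", "1")))
      NA_integer_
    else sum(a == "1")
  }, integer(1))
}

#' Read a bulk-sequencing VCF into a BulkSnpSet
#'
#' Ingests a multi-sample VCF (plain or bgzipped) with per-sample allelic
#' depths (`AD`), keeps biallelic SNPs, and records every exclusion class in
#' an ingestion report. When both parents are named, sites are polarized so
#' that the `alt` allele is the allele carried homozygously by the high-trait
#' parent (see [polarizeSites()]).
#'
#' Records are excluded (and counted) when they are not biallelic, are
#' indels (unless `keepIndels = TRUE`), or carry a missing/malformed `AD` in
#' either bulk. Missing `AD` is an exclusion, never a silent zero fill: a
#' zero-filled site would slip through the depth filter downstream.
#'
#' @param path VCF file.
#' @param bulkA,bulkB sample names of the two bulks (A is conventionally the
#'   high-trait bulk).
#' @param parentHigh,parentLow optional sample names of the high-/low-trait
#'   parents, used for polarization and for the parental-mean SNP-index
#'   option of [computeSnpStats()].
#' @param keepIndels admit indel records (default drops them; the scan
#'   statistics are allele-frequency based and allele-length-agnostic, but
#'   the default matches a SNP-only scan).
#' @param genome genome label passed to [VariantAnnotation::readVcf()].
#'
#' @return A [BulkSnpSet-class], sorted by (chrom, pos), with the ingestion
#'   report in [ingestReport()]. No depth filter is applied; see
#'   [filterDepth()].
#' @export
readBulkVcf <- function(path, bulkA, bulkB,
                        parentHigh = NULL, parentLow = NULL,
                        keepIndels = FALSE, genome = "unknown") {
  if (!file.exists(path))
    stop("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = genome)
  hdr <- VariantAnnotation::header(vcf)
  samples <- VariantAnnotation::samples(hdr)
  need <- c(bulkA, bulkB, parentHigh, parentLow)
  missingSamples <- setdiff(need, samples)
  if (length(missingSamples))
    stop("sample(s) not present in VCF: ", paste(missingSamples, collapse = ", "))
  if (!"AD" %in% rownames(VariantAnnotation::geno(hdr)))
    stop("VCF has no per-sample AD FORMAT field")

  nTotal <- nrow(vcf)
  report <- newIngestReport(nTotal = nTotal)
  if (nTotal == 0L) {
    out <- BulkSnpSet(character(), integer(), character(), character(),
                      integer(), integer(), integer(), integer(),
                      bulkNames = c(bulkA, bulkB), ingestReport = report)
    return(out)
  }

  nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  keep <- nAlt == 1L
  report$nMultiallelicDropped <- sum(!keep)
  vcf <- vcf[keep, ]

  refStr <- as.character(VariantAnnotation::ref(vcf))
  altStr <- as.character(unlist(VariantAnnotation::alt(vcf)))
  if (!keepIndels) {
    snp <- nchar(refStr) == 1L & nchar(altStr) == 1L &
      grepl("^[ACGTN]$", refStr) & grepl("^[ACGTN]$", altStr)
    report$nIndelDropped <- sum(!snp)
    vcf <- vcf[snp, ]
    refStr <- refStr[snp]
    altStr <- altStr[snp]
  }

  ad <- VariantAnnotation::geno(vcf)$AD
  adA <- .adColumns(ad, bulkA)
  adB <- .adColumns(ad, bulkB)
  ok <- !is.na(adA$ref) & !is.na(adA$alt) & !is.na(adB$ref) & !is.na(adB$alt) &
    adA$len == 2L & adB$len == 2L
  report$nMissingAdDropped <- sum(!ok)
  vcf <- vcf[ok, ]
  refStr <- refStr[ok]
  altStr <- altStr[ok]
  report$nRetained <- nrow(vcf)

  rr <- SummarizedExperiment::rowRanges(vcf)
  sl <- GenomeInfoDb::seqlengths(rr)
  x <- BulkSnpSet(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                  pos = BiocGenerics::start(rr),
                  ref = refStr, alt = altStr,
                  adRefA = adA$ref[ok], adAltA = adA$alt[ok],
                  adRefB = adB$ref[ok], adAltB = adB$alt[ok],
                  polarized = FALSE,
                  bulkNames = c(bulkA, bulkB),
                  seqlengths = if (!all(is.na(sl))) sl else NULL,
                  ingestReport = report)

  if (!is.null(parentHigh) || !is.null(parentLow)) {
    gt <- VariantAnnotation::geno(vcf)$GT
    o <- BiocGenerics::order(SummarizedExperiment::rowRanges(vcf))
    gtHigh <- if (!is.null(parentHigh)) .gtDosage(gt[, parentHigh])[o] else NULL
    gtLow <- if (!is.null(parentLow)) .gtDosage(gt[, parentLow])[o] else NULL
    if (!is.null(parentHigh)) {
      p <- .adColumns(ad, parentHigh)
      ph <- cbind(ref = p$ref[ok], alt = p$alt[ok])[o, , drop = FALSE]
      S4Vectors::metadata(x)$parentHighDepth <- ph
    }
    if (!is.null(parentLow)) {
      p <- .adColumns(ad, parentLow)
      pl <- cbind(ref = p$ref[ok], alt = p$alt[ok])[o, , drop = FALSE]
      S4Vectors::metadata(x)$parentLowDepth <- pl
    }
    x <- polarizeSites(x, gtHigh = gtHigh, gtLow = gtLow)
  }
  x
}

## swap ref/alt orientation of the selected sites, in both bulks (and in any
## stored parent depths), keeping everything else fixed
.swapOrientation <- function(x, swap) {
  if (!any(swap)) return(x)
  adRef <- SummarizedExperiment::assay(x, "adRef")
  adAlt <- SummarizedExperiment::assay(x, "adAlt")
  tmp <- adRef[swap, , drop = FALSE]
  adRef[swap, ] <- adAlt[swap, , drop = FALSE]
  adAlt[swap, ] <- tmp
  SummarizedExperiment::assay(x, "adRef") <- adRef
  SummarizedExperiment::assay(x, "adAlt") <- adAlt
  rd <- SummarizedExperiment::rowData(x)
  tmp <- rd$ref[swap]
  rd$ref[swap] <- rd$alt[swap]
  rd$alt[swap] <- tmp
  SummarizedExperiment::rowData(x) <- rd
  for (nm in c("parentHighDepth", "parentLowDepth")) {
    m <- S4Vectors::metadata(x)[[nm]]
    if (!is.null(m)) {
      m[swap, ] <- m[swap, c(2L, 1L), drop = FALSE]
      S4Vectors::metadata(x)[[nm]] <- m
    }
  }
  x
}

#' Polarize sites by parental origin
#'
#' Reorients each site so that the `alt` allele is the allele carried
#' homozygously by the high-trait parent, which fixes the sign convention of
#' the Delta-SNP-index (high minus low). When the high parent is homozygous
#' for the current reference allele, the ref/alt labels and the depth pairs
#' of both bulks are swapped. Sites where either supplied parent call is
#' heterozygous or missing (or where the two parents do not carry opposite
#' homozygous alleles) are flagged unpolarizable (`NA`): they are excluded
#' from signed Delta scans but retained for |Delta|, G and ED.
#'
#' Applying the underlying orientation swap twice restores the original
#' orientation; polarizing an already polarized set with correspondingly
#' updated parent dosages is a no-op.
#'
#' @param x a [BulkSnpSet-class].
#' @param gtHigh,gtLow integer ALT-dosage of the high/low parent per site
#'   (0 = homozygous ref, 1 = het, 2 = homozygous alt, NA = missing).
#'   `gtLow` may be `NULL` if only the high parent was genotyped.
#' @return `x` with orientation fixed and the `polarized` flag set.
#' @export
polarizeSites <- function(x, gtHigh, gtLow = NULL) {
  n <- length(x)
  if (is.null(gtHigh))
    stop("polarization requires at least the high-trait parent genotypes")
  stopifnot(length(gtHigh) == n, is.null(gtLow) || length(gtLow) == n)
  if (is.null(gtLow)) {
    polarizable <- gtHigh %in% c(0L, 2L)
    swap <- polarizable & gtHigh == 0L
  } else {
    polarizable <- (gtHigh %in% c(0L, 2L)) & (gtLow %in% c(0L, 2L)) &
      (gtHigh + gtLow == 2L)
    swap <- polarizable & gtHigh == 0L
  }
  x <- .swapOrientation(x, swap)
  rd <- SummarizedExperiment::rowData(x)
  rd$polarized <- ifelse(polarizable, TRUE, NA)
  SummarizedExperiment::rowData(x) <- rd
  x
}

#' Discard sites with low coverage in either bulk
#'
#' Applies the BSA depth filter: a site is retained only when its total read
#' depth (`ref + alt`) is at least `minDepth` in *both* bulks; the rule is a
#' strict `< minDepth` discard, so totals of exactly `minDepth` are kept.
#' Site order is preserved and the operation is idempotent.
#'
#' @param x a [BulkSnpSet-class].
#' @param minDepth minimum per-bulk total depth (default 10).
#' @return The filtered `BulkSnpSet`; the number of sites removed is added to
#'   `ingestReport(x)$nDepthFiltered` and recorded in
#'   `metadata(x)$depthFilter`.
#' @examples
#' x <- BulkSnpSet("Chr01", 1:2, "A", "G",
#'                 adRefA = c(4, 6), adAltA = c(5, 6),
#'                 adRefB = c(20, 6), adAltB = c(10, 6))
#' length(filterDepth(x, 10))  # first site has bulk A total 9 -> removed
#' @export
filterDepth <- function(x, minDepth = 10L) {
  stopifnot(minDepth >= 0)
  tot <- totalDepth(x)
  keep <- tot[, 1L] >= minDepth & tot[, 2L] >= minDepth
  nRemoved <- sum(!keep)
  out <- x[keep, ]
  rep <- ingestReport(out)
  if (!is.null(rep)) {
    rep$nDepthFiltered <- rep$nDepthFiltered + nRemoved
    rep$nRetained <- rep$nRetained - nRemoved
    ingestReport(out) <- rep
  }
  S4Vectors::metadata(out)$depthFilter <-
    list(minDepth = minDepth, nRemoved = nRemoved)
  out
}

#' Write a BulkSnpSet as a VCF
#'
#' Emits a valid VCF 4.2 file with `##contig` header lines and per-sample
#' `GT`/`AD` fields (through [VariantAnnotation::writeVcf()]), such that
#' [readBulkVcf()] on the result recovers the same sites and depths exactly.
#' Used to round-trip simulator output.
#'
#' @param x a sorted [BulkSnpSet-class].
#' @param path output file (".vcf"; VariantAnnotation compresses when the
#'   path ends in ".gz").
#' @param contigLengths named vector of contig lengths; defaults to
#'   `seqlengths(x)` and must cover every site position.
#' @return `path`, invisibly.
#' @export
writeBulkVcf <- function(x, path, contigLengths = NULL) {
  n <- length(x)
  rr <- SummarizedExperiment::rowRanges(x)
  o <- BiocGenerics::order(rr)
  if (n && !identical(o, seq_len(n)))
    stop("sites must be sorted by (chrom, pos) before writing")
  if (is.null(contigLengths)) {
    contigLengths <- GenomeInfoDb::seqlengths(rr)
    if (length(contigLengths) == 0L || anyNA(contigLengths))
      stop("contigLengths missing: supply them or set seqlengths on the object")
  }
  chroms <- as.character(GenomeInfoDb::seqnames(rr))
  if (n) {
    if (!all(chroms %in% names(contigLengths)))
      stop("contigLengths does not cover all chromosomes")
    if (any(BiocGenerics::end(rr) > contigLengths[chroms]))
      stop("site position beyond contig length")
  }

  gr <- GenomicRanges::GRanges(
    seqnames = factor(chroms, levels = names(contigLengths)),
    ranges = IRanges::ranges(rr),
    seqinfo = GenomeInfoDb::Seqinfo(names(contigLengths),
                                    seqlengths = unname(contigLengths)))
  rd <- SummarizedExperiment::rowData(x)
  adRef <- refDepth(x)
  adAlt <- altDepth(x)
  admat <- matrix(mapply(function(r, a) c(r, a),
                         as.vector(adRef), as.vector(adAlt),
                         SIMPLIFY = FALSE),
                  nrow = n, ncol = 2L,
                  dimnames = list(NULL, bulkNames(x)))
  gt <- matrix("./.", nrow = n, ncol = 2L,
               dimnames = list(NULL, bulkNames(x)))

  hdr <- VariantAnnotation::VCFHeader(samples = bulkNames(x))
  VariantAnnotation::geno(hdr) <- S4Vectors::DataFrame(
    Number = c("1", "R"), Type = c("String", "Integer"),
    Description = c("Genotype",
                    "Allelic depths for the ref and alt alleles"),
    row.names = c("GT", "AD"))
  VariantAnnotation::meta(hdr)$fileformat <-
    S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat")

  vcf <- VariantAnnotation::VCF(
    rowRanges = gr,
    colData = S4Vectors::DataFrame(Samples = seq_len(2L),
                                   row.names = bulkNames(x)),
    exptData = list(header = hdr),
    fixed = S4Vectors::DataFrame(
      REF = Biostrings::DNAStringSet(rd$ref),
      ALT = Biostrings::DNAStringSetList(as.list(rd$alt)),
      QUAL = rep(NA_real_, n),
      FILTER = rep("PASS", n)),
    geno = S4Vectors::SimpleList(GT = gt, AD = admat))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

#' Export the site table as TSV
#'
#' One row per site: `chrom`, `pos`, `ref`, `alt`, `ad_a_ref`, `ad_a_alt`,
#' `ad_b_ref`, `ad_b_alt`, `polarized` (`.` for unpolarizable sites).
#'
#' @param x a [BulkSnpSet-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
exportSiteTable <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  adRef <- refDepth(x)
  adAlt <- altDepth(x)
  pol <- isPolarized(x)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    pos = BiocGenerics::start(x),
    ref = rd$ref, alt = rd$alt,
    ad_a_ref = adRef[, 1L], ad_a_alt = adAlt[, 1L],
    ad_b_ref = adRef[, 2L], ad_b_alt = adAlt[, 2L],
    polarized = ifelse(is.na(pol), ".", as.character(pol)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
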