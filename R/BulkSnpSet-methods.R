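#' @include AllGenerics.R AllClasses.R
NULL

#' @describeIn BulkSnpSet-class integer matrix of reference-allele depths
#'   (columns = bulks).
#' @param x a `BulkSnpSet`.
#' @export
setMethod("refDepth", "BulkSnpSet", function(x)
  SummarizedExperiment::assay(x, "adRef"))

#' @describeIn BulkSnpSet-class integer matrix of alternate-allele depths.
#' @export
setMethod("altDepth", "BulkSnpSet", function(x)
  SummarizedExperiment::assay(x, "adAlt"))

#' @describeIn BulkSnpSet-class per-bulk total depth (`adRef + adAlt`).
#' @export
setMethod("totalDepth", "BulkSnpSet", function(x)
  refDepth(x) + altDepth(x))

#' @describeIn BulkSnpSet-class per-site polarization flag (`TRUE` /
#'   `FALSE` / `NA` = unpolarizable).
#' @export
setMethod("isPolarized", "BulkSnpSet", function(x)
  SummarizedExperiment::rowData(x)$polarized)

#' @describeIn BulkSnpSet-class the two bulk sample names.
#' @export
setMethod("bulkNames", "BulkSnpSet", function(x) colnames(x))

#' @describeIn BulkSnpSet-class ingestion/filter counters: `nTotal`,
#'   `nMultiallelicDropped`, `nIndelDropped`, `nMissingAdDropped`,
#'   `nDepthFiltered`, `nRetained`. The retained plus dropped/filtered
#'   counts always sum to `nTotal`.
#' @export
setMethod("ingestReport", "BulkSnpSet", function(x)
  S4Vectors::metadata(x)$ingestReport)

#' @describeIn BulkSnpSet-class replace the ingestion report.
#' @param value a list of counters.
#' @export
setMethod("ingestReport<-", "BulkSnpSet", function(x, value) {
  S4Vectors::metadata(x)$ingestReport <- value
  x
})

setMethod("show", "BulkSnpSet", function(object) {
  methods::callNextMethod()
  rep <- ingestReport(object)
  if (!is.null(rep))
    cat(sprintf("ingest: %d read, %d retained (%d multiallelic, %d indel, %d missing-AD, %d depth-filtered)\n",
                rep$nTotal, rep$nRetained, rep$nMultiallelicDropped,
                rep$nIndelDropped, rep$nMissingAdDropped, rep$nDepthFiltered))
  pol <- isPolarized(object)
  if (length(pol))
    cat(sprintf("polarized: %d TRUE, %d FALSE, %d unpolarizable\n",
                sum(pol %in% TRUE), sum(pol %in% FALSE), sum(is.na(pol))))
})
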