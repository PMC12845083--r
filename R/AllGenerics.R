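#' @export
setGeneric("refDepth", function(x, ...) standardGeneric("refDepth"))

#' @export
setGeneric("altDepth", function(x, ...) standardGeneric("altDepth"))

#' @export
setGeneric("totalDepth", function(x, ...) standardGeneric("totalDepth"))

#' @export
setGeneric("isPolarized", function(x, ...) standardGeneric("isPolarized"))

#' @export
setGeneric("bulkNames", function(x, ...) standardGeneric("bulkNames"))

#' @export
setGeneric("ingestReport", function(x, ...) standardGeneric("ingestReport"))

#' @export
setGeneric("ingestReport<-", function(x, value) standardGeneric("ingestReport<-"))

#' @export
setGeneric("thresholdFor",
           function(x, statistic, level, chrom = "genome")
             standardGeneric("thresholdFor"))
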