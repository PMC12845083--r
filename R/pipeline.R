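#' @include AllClasses.R variant-io.R bsa-stats.R genome-scan.R segregation.R simulate.R
NULL

.logLine <- function(logFile, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE, sep = "")
}

.writeParams <- function(outDir, params) {
  path <- file.path(outDir, "params.json")
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

## run `expr`, removing every file it created under outDir on failure so a
## failed run never leaves partial outputs behind
.withCleanOutputs <- function(outDir, expr) {
  before <- list.files(outDir, recursive = TRUE, full.names = TRUE)
  tryCatch(expr, error = function(e) {
    after <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    unlink(setdiff(after, before))
    stop(e)
  })
}

#' Run the complete BSA scan workflow on a VCF
#'
#' Ingests the VCF, applies the depth filter, computes per-SNP statistics,
#' window smoothing, permutation thresholds and candidate intervals, and
#' writes the full output bundle to `outDir`: `sites.tsv`, `snp_stats.tsv`,
#' `windows.tsv`, `thresholds.tsv`, `intervals.bed`, `ingest_report.tsv`,
#' `params.json` (machine-readable parameter record), per-statistic plots,
#' and `scan.log`. With the same config and seed, the TSV outputs are
#' byte-identical across runs.
#'
#' @param vcf input VCF path.
#' @param bulkA,bulkB,parentHigh,parentLow sample names, see
#'   [readBulkVcf()].
#' @param outDir output directory (created if needed).
#' @param config a [ScanConfig-class].
#' @param minDepth per-bulk total-depth filter (default 10).
#' @param highBulk which bulk is the high-trait bulk.
#' @param statistics statistics to scan (`"delta"`, `"gprime"`, `"ed4"`).
#' @param plot write per-statistic scan plots (PDF).
#' @return invisibly, the [bsaScan()] result list.
#' @export
runScan <- function(vcf, bulkA, bulkB, parentHigh = NULL, parentLow = NULL,
                    outDir, config = scanConfig(), minDepth = 10L,
                    highBulk = "A",
                    statistics = c("delta", "gprime", "ed4"), plot = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "scan.log")
  .withCleanOutputs(outDir, {
    .logLine(logFile, "scan: ingesting ", vcf)
    x <- readBulkVcf(vcf, bulkA, bulkB, parentHigh, parentLow)
    rep <- ingestReport(x)
    .logLine(logFile, sprintf("scan: %d records read, %d biallelic SNPs retained",
                              rep$nTotal, rep$nRetained))
    x <- filterDepth(x, minDepth)
    .logLine(logFile, sprintf("scan: %d sites after depth filter (>= %dx in both bulks)",
                              length(x), as.integer(minDepth)))
    if (length(x) == 0L)
      stop("no sites retained after filtering")
    .writeParams(outDir, list(
      subcommand = "scan", vcf = vcf, bulkA = bulkA, bulkB = bulkB,
      parentHigh = parentHigh, parentLow = parentLow,
      minDepth = as.integer(minDepth), highBulk = highBulk,
      statistics = statistics,
      windowSize = config@windowSize, stepSize = config@stepSize,
      tricubeHalfwidth = config@tricubeHalfwidth,
      nPermutations = config@nPermutations, levels = config@levels,
      seed = config@seed, permScheme = config@permScheme, pool = config@pool,
      package = as.character(utils::packageVersion("BSAscan"))))
    res <- bsaScan(x, config, highBulk = highBulk, statistics = statistics)
    exportSiteTable(x, file.path(outDir, "sites.tsv"))
    exportStatTable(res$snpStats, file.path(outDir, "snp_stats.tsv"))
    exportWindowTable(res$windows, file.path(outDir, "windows.tsv"))
    exportThresholdTable(res$thresholds, file.path(outDir, "thresholds.tsv"))
    exportIntervalsBed(res$intervals, file.path(outDir, "intervals.bed"))
    utils::write.table(data.frame(counter = names(rep),
                                  value = unlist(rep)),
                       file.path(outDir, "ingest_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (plot) {
      for (s in statistics) {
        grDevices::pdf(file.path(outDir, paste0("scan_", s, ".pdf")),
                       width = 8, height = 4)
        print(plotScan(res$windows, res$thresholds, s))
        grDevices::dev.off()
      }
    }
    .logLine(logFile, sprintf("scan: %d candidate interval(s) written",
                              length(res$intervals)))
    invisible(res)
  })
}

#' Run the segregation-ratio test workflow
#'
#' Reads a table of labelled two-class phenotype counts (TSV with columns
#' `label`, `a`, `b` and optionally `class`), scans 1..`maxGenes` duplicate
#' gene models for each, and writes the segregation table.
#'
#' @param input TSV path or a data.frame.
#' @param outFile output TSV path (optional).
#' @param maxGenes models tested per contrast.
#' @return the report data.frame, invisibly when writing.
#' @export
runSegTest <- function(input, outFile = NULL, maxGenes = 4L) {
  counts <- if (is.data.frame(input)) input
            else utils::read.table(input, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE)
  report <- segregationReport(counts, maxGenes = maxGenes)
  if (!is.null(outFile)) {
    utils::write.table(report, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(report))
  }
  report
}

#' Run the simulator workflow
#'
#' Simulates a RIL bulk-sequencing design and writes `simulated.vcf` (which
#' re-ingests cleanly with [readBulkVcf()]), `truth.tsv` with the true bulk
#' allele frequencies, and `params.json`.
#'
#' @param scenario a [SimScenario-class].
#' @param outDir output directory.
#' @return invisibly, the [simulateBulks()] result.
#' @export
runSimulate <- function(scenario, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  .withCleanOutputs(outDir, {
    sim <- simulateBulks(scenario)
    writeBulkVcf(sim$sites, file.path(outDir, "simulated.vcf"))
    utils::write.table(sim$truth, file.path(outDir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeParams(outDir, list(
      subcommand = "simulate",
      chromosomes = scenario@chromosomes,
      markerSpacing = scenario@markerSpacing,
      recombRate = scenario@recombRate,
      qtl = scenario@qtl,
      nLinesPerBulk = scenario@nLinesPerBulk,
      generation = scenario@generation,
      meanDepth = scenario@meanDepth,
      depthModel = scenario@depthModel,
      seed = scenario@seed,
      package = as.character(utils::packageVersion("BSAscan"))))
    invisible(sim)
  })
}

#' Run the power-analysis workflow
#'
#' @param scenarios list of [SimScenario-class] objects.
#' @param config a [ScanConfig-class].
#' @param nReps replicates per scenario.
#' @param seed master seed.
#' @param outFile optional output TSV.
#' @return the power table (see [powerAnalysis()]).
#' @export
runPower <- function(scenarios, config = scanConfig(), nReps = 10L, seed = 1L,
                     outFile = NULL) {
  tab <- powerAnalysis(scenarios, config, nReps = nReps, seed = seed)
  if (!is.null(outFile))
    utils::write.table(tab, outFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
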