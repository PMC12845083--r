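#' @include AllGenerics.R AllClasses.R
NULL

#' Expected recombinant fraction between two loci in selfed RILs
#'
#' Converts a map distance to a single-meiosis recombination fraction with
#' the Haldane map function, `r = (1 - exp(-2 d / 100)) / 2`, and then to
#' the expected fraction of recombinant inbred lines (by repeated selfing to
#' fixation) recombinant between the loci, `R = 2 r / (1 + 2 r)`.
#' Accumulated recombination over the selfing generations makes `R > r` for
#' linked loci; both approach 1/2 for unlinked loci.
#'
#' @param mapDistance map distance in cM (vectorized, `>= 0`).
#' @return `R` in `[0, 0.5]`.
#' @examples
#' rilRecombFraction(c(0, 10, 1000))
#' @export
rilRecombFraction <- function(mapDistance) {
  stopifnot(all(mapDistance >= 0))
  r <- (1 - exp(-2 * mapDistance / 100)) / 2
  2 * r / (1 + 2 * r)
}

## simulate the high-allele indicator of nLines RIL genomes along one
## chromosome as a Markov chain over markers with per-interval switch
## probability R; optionally conditioned on the allele at a QTL marker
.simLineGenotypes <- function(nLines, pos, recombRate, qtlIdx = NA,
                              qtlAllele = NULL) {
  nM <- length(pos)
  g <- matrix(0L, nrow = nLines, ncol = nM)
  Rstep <- rilRecombFraction(recombRate * diff(pos) / 1e6)
  if (is.na(qtlIdx)) {
    g[, 1L] <- stats::rbinom(nLines, 1L, 0.5)
    for (j in seq_len(nM - 1L)) {
      flip <- stats::rbinom(nLines, 1L, Rstep[j])
      g[, j + 1L] <- bitwXor(g[, j], flip)
    }
  } else {
    g[, qtlIdx] <- qtlAllele
    if (qtlIdx < nM) for (j in qtlIdx:(nM - 1L)) {  # rightwards from the QTL
      flip <- stats::rbinom(nLines, 1L, Rstep[j])
      g[, j + 1L] <- bitwXor(g[, j], flip)
    }
    if (qtlIdx > 1L) for (j in qtlIdx:2L) {         # leftwards from the QTL
      flip <- stats::rbinom(nLines, 1L, Rstep[j - 1L])
      g[, j - 1L] <- bitwXor(g[, j], flip)
    }
  }
  g
}

#' Simulate bulk-segregant sequencing data from a RIL design
#'
#' Generates synthetic data with the statistical structure the genome scan
#' assumes. Each bulk pools `nLinesPerBulk` near-homozygous RILs; line
#' genomes are Markov chains over the marker grid with switch probabilities
#' from [rilRecombFraction()] (Haldane map, no interference). At a QTL, a
#' line selected into the high bulk carries the high-trait allele with
#' probability `effect` (and a low-bulk line with probability `1 - effect`),
#' emulating selection of phenotypically extreme lines. Residual
#' heterozygosity is modelled per locus, independently, with probability
#' `(1/2)^(generation - 1)`; a heterozygous locus contributes allele
#' frequency 1/2 to its line. Read depths are drawn per site per bulk from
#' the configured depth model and alternate-read counts are binomial in the
#' true bulk allele frequency.
#'
#' Sites are polarized by construction: the `alt` allele is the high-trait
#' parent allele.
#'
#' @param scenario a [SimScenario-class]; its `seed` (when not `NA`) makes
#'   the draw bit-reproducible.
#' @return list with elements `sites` (a [BulkSnpSet-class], bulk A = high
#'   bulk) and `truth` (data.frame `chrom`, `pos`, `freqHigh`, `freqLow`,
#'   `isCausal` of true per-marker bulk allele frequencies).
#' @examples
#' sc <- simScenario(chromosomes = data.frame(name = "Chr01", length = 2e6),
#'                   markerSpacing = 1e5,
#'                   qtl = data.frame(chrom = "Chr01", pos = 1e6, effect = 1),
#'                   seed = 1)
#' sim <- simulateBulks(sc)
#' sim$truth[sim$truth$isCausal, ]
#' @export
simulateBulks <- function(scenario) {
  methods::validObject(scenario)
  if (!is.na(scenario@seed)) set.seed(scenario@seed)
  hetProb <- 0.5^(scenario@generation - 1L)
  nLines <- scenario@nLinesPerBulk

  allChrom <- character(0); allPos <- numeric(0)
  freqHigh <- numeric(0); freqLow <- numeric(0); isCausal <- logical(0)
  for (i in seq_len(nrow(scenario@chromosomes))) {
    ch <- scenario@chromosomes$name[i]
    len <- scenario@chromosomes$length[i]
    pos <- seq(scenario@markerSpacing, len, by = scenario@markerSpacing)
    qrow <- which(scenario@qtl$chrom == ch)
    qtlIdx <- NA
    if (length(qrow)) {
      qpos <- scenario@qtl$pos[qrow]
      pos <- sort(unique(c(pos, qpos)))
      qtlIdx <- match(qpos, pos)
    }
    bulkFreq <- function(selectProb) {
      qa <- if (!is.na(qtlIdx))
        stats::rbinom(nLines, 1L, selectProb) else NULL
      g <- .simLineGenotypes(nLines, pos, scenario@recombRate, qtlIdx, qa)
      het <- matrix(stats::rbinom(length(g), 1L, hetProb) == 1L,
                    nrow = nrow(g))
      v <- ifelse(het, 0.5, g)
      colMeans(v)
    }
    eff <- if (length(qrow)) scenario@qtl$effect[qrow] else NA
    fH <- bulkFreq(if (is.na(eff)) NA else eff)
    fL <- bulkFreq(if (is.na(eff)) NA else 1 - eff)
    allChrom <- c(allChrom, rep(ch, length(pos)))
    allPos <- c(allPos, pos)
    freqHigh <- c(freqHigh, fH)
    freqLow <- c(freqLow, fL)
    isCausal <- c(isCausal, if (!is.na(qtlIdx))
      seq_along(pos) == qtlIdx else rep(FALSE, length(pos)))
  }

  nSites <- length(allPos)
  drawDepth <- function() {
    if (scenario@depthModel == "fixed") rep(round(scenario@meanDepth), nSites)
    else stats::rpois(nSites, scenario@meanDepth)
  }
  depthH <- drawDepth(); depthL <- drawDepth()
  altH <- stats::rbinom(nSites, depthH, freqHigh)
  altL <- stats::rbinom(nSites, depthL, freqLow)

  seqlens <- stats::setNames(scenario@chromosomes$length,
                             scenario@chromosomes$name)
  sites <- BulkSnpSet(chrom = allChrom, pos = allPos,
                      ref = "A", alt = "T",
                      adRefA = depthH - altH, adAltA = altH,
                      adRefB = depthL - altL, adAltB = altL,
                      polarized = TRUE,
                      bulkNames = c("highBulk", "lowBulk"),
                      seqlengths = seqlens,
                      metadata = list(scenario = scenario))
  truth <- data.frame(chrom = allChrom, pos = allPos,
                      freqHigh = freqHigh, freqLow = freqLow,
                      isCausal = isCausal)
  list(sites = sites, truth = truth)
}

#' Null sites with pure binomial read sampling
#'
#' A minimal exchangeable-null generator used for threshold calibration:
#' every site gets fixed `depth` in both bulks and alternate-read counts
#' drawn independently as `Binomial(depth, p)` in each bulk — no linkage,
#' no bulk structure, no QTL.
#'
#' @param nSnps number of sites.
#' @param depth per-bulk read depth.
#' @param p alternate-allele frequency in both bulks.
#' @param spacing marker spacing in bp.
#' @param chrom chromosome name.
#' @return an unpolarized [BulkSnpSet-class].
#' @export
simulateNullBulks <- function(nSnps = 2000L, depth = 30L, p = 0.5,
                              spacing = 1e4, chrom = "Chr01") {
  pos <- spacing * seq_len(nSnps)
  altA <- stats::rbinom(nSnps, depth, p)
  altB <- stats::rbinom(nSnps, depth, p)
  BulkSnpSet(chrom = chrom, pos = pos, ref = "A", alt = "T",
             adRefA = depth - altA, adAltA = altA,
             adRefB = depth - altB, adAltB = altB,
             polarized = FALSE,
             seqlengths = stats::setNames(spacing * (nSnps + 1L), chrom))
}

#' Power and calibration analysis over simulated scenarios
#'
#' For each scenario, simulates `nReps` replicate designs, runs the full
#' scan (statistics, permutation thresholds, interval calling) and records,
#' per statistic, the fraction of replicates in which a called interval
#' covers the true causal position (coverage; `NA` for null scenarios) and
#' the fraction of windows exceeding the threshold (the false-positive
#' window rate on null scenarios).
#'
#' @param scenarios list of [SimScenario-class] objects.
#' @param config a [ScanConfig-class] used for every scan.
#' @param nReps replicates per scenario.
#' @param seed master seed; replicate seeds are derived from it.
#' @param level confidence level used for interval calling.
#' @param maxTotalPermutations guard against runaway desk-scale runs: a
#'   warning is emitted when `scenarios * reps * permutations` exceeds it.
#' @return data.frame with one row per scenario x statistic: `scenario`,
#'   `statistic`, `nReps`, `coverage`, `fpWindowRate`.
#' @export
powerAnalysis <- function(scenarios, config = scanConfig(), nReps = 10L,
                          seed = 1L, level = 0.95,
                          maxTotalPermutations = 1e7) {
  if (nReps == 0L || !length(scenarios))
    return(data.frame(scenario = integer(0), statistic = character(0),
                      nReps = integer(0), coverage = numeric(0),
                      fpWindowRate = numeric(0)))
  totalPerm <- length(scenarios) * nReps * as.numeric(config@nPermutations)
  if (totalPerm > maxTotalPermutations)
    warning("large run: ", format(totalPerm, big.mark = ","),
            " total permutations requested")
  statistics <- c("delta", "gprime", "ed4")
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    covered <- matrix(NA, nrow = nReps, ncol = length(statistics),
                      dimnames = list(NULL, statistics))
    fpRate <- matrix(NA_real_, nrow = nReps, ncol = length(statistics),
                     dimnames = list(NULL, statistics))
    for (rep in seq_len(nReps)) {
      scr <- sc
      scr@seed <- as.integer((seed * 1000L + si * 100L + rep) %% .Machine$integer.max)
      cfg <- config
      cfg@seed <- scr@seed + 1L
      sim <- simulateBulks(scr)
      x <- filterDepth(sim$sites)
      scan <- bsaScan(x, cfg, statistics = statistics)
      hasQtl <- nrow(sc@qtl) > 0
      for (s in statistics) {
        iv <- scan$intervals[S4Vectors::mcols(scan$intervals)$statistic == s &
                             S4Vectors::mcols(scan$intervals)$level == level]
        if (hasQtl) {
          qgr <- GenomicRanges::GRanges(sc@qtl$chrom,
                                        IRanges::IRanges(sc@qtl$pos, width = 1))
          covered[rep, s] <- length(iv) > 0 &&
            any(GenomicRanges::countOverlaps(qgr, iv) > 0)
        } else {
          colMap <- c(delta = "meanDelta", gprime = "gprime", ed4 = "meanEd4")
          vals <- S4Vectors::mcols(scan$windows)[[colMap[[s]]]]
          thr <- thresholdFor(scan$thresholds, s, level)
          fpRate[rep, s] <- mean(vals >= thr, na.rm = TRUE)
        }
      }
    }
    for (s in statistics)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = si, statistic = s, nReps = nReps,
        coverage = mean(covered[, s]),
        fpWindowRate = mean(fpRate[, s]))
  }
  do.call(rbind, rows)
}
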