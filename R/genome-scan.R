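#' @include AllGenerics.R AllClasses.R bsa-stats.R
NULL

#' Tricube kernel weight
#'
#' `w(d) = (1 - (|d|/h)^3)^3` for `|d| <= h`, 0 beyond the half-width `h`.
#' Used for distance-decayed local averaging of the G statistic (G-prime).
#'
#' @param distance genomic offset in bp (vectorized).
#' @param halfwidth kernel half-width in bp (> 0).
#' @return weights in `[0, 1]`.
#' @examples
#' tricubeWeight(c(0, 250e3, 500e3), 500e3)
#' @export
tricubeWeight <- function(distance, halfwidth) {
  stopifnot(halfwidth > 0)
  u <- abs(distance) / halfwidth
  ifelse(u <= 1, (1 - u^3)^3, 0)
}

## sparse tricube weight matrix: rows = evaluation positions, columns = SNPs
## (both within one chromosome, snpPos sorted ascending)
.tricubeMatrix <- function(evalPos, snpPos, halfwidth) {
  lo <- findInterval(evalPos - halfwidth, snpPos, left.open = TRUE) + 1L
  hi <- findInterval(evalPos + halfwidth, snpPos)
  counts <- pmax(hi - lo + 1L, 0L)
  rows <- rep.int(seq_along(evalPos), counts)
  cols <- sequence(counts, from = lo)
  Matrix::sparseMatrix(i = rows, j = cols,
                       x = tricubeWeight(snpPos[cols] - evalPos[rows], halfwidth),
                       dims = c(length(evalPos), length(snpPos)))
}

#' Tricube-smoothed G statistic (G-prime)
#'
#' For each SNP, G-prime is the tricube-weighted mean of the G statistics of
#' all SNPs within `halfwidth` bp on the same chromosome (the SNP itself
#' included with weight 1). A single isolated SNP therefore keeps its own G.
#'
#' @param stats sorted per-SNP statistics from [computeSnpStats()].
#' @param halfwidth kernel half-width in bp.
#' @param column metadata column to smooth (default `"g"`).
#' @return numeric vector of smoothed values aligned with `stats`.
#' @export
gprimeSmooth <- function(stats, halfwidth, column = "g") {
  v <- S4Vectors::mcols(stats)[[column]]
  pos <- BiocGenerics::start(stats)
  chrom <- as.character(GenomeInfoDb::seqnames(stats))
  out <- rep(NA_real_, length(v))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (is.unsorted(pos[i]))
      stop("stats must be sorted by position within chromosome")
    M <- .tricubeMatrix(pos[i], pos[i], halfwidth)
    vi <- v[i]
    num <- as.vector(M %*% ifelse(is.na(vi), 0, vi))
    den <- as.vector(M %*% as.numeric(!is.na(vi)))
    out[i] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

## ---------------------------------------------------------------------------
## scan structure: everything about window membership and kernel weights that
## depends only on SNP *positions*, precomputed once and reused across
## permutation replicates (depths change, positions do not)
## ---------------------------------------------------------------------------
.scanStructure <- function(pos, chrom, seqlens, config, polarized) {
  stopifnot(!is.unsorted(match(chrom, unique(chrom))))
  W <- config@windowSize
  step <- config@stepSize
  chroms <- unique(chrom)
  winChrom <- character(0)
  winStart <- numeric(0)
  lo <- integer(0)
  hi <- integer(0)
  Ms <- list()
  offset <- 0L
  for (ch in chroms) {
    i <- which(chrom == ch)
    p <- pos[i]
    if (is.unsorted(p))
      stop("sites must be sorted by position within chromosome")
    len <- seqlens[ch]
    if (is.null(len) || is.na(len)) len <- max(p)
    starts <- seq(0, max(0, len - W), by = step)
    p0 <- p - 1L                      # windows use 0-based half-open arithmetic
    wlo <- findInterval(starts, p0, left.open = TRUE) + 1L
    whi <- findInterval(starts + W - 1L, p0)   # p0 <= start+W-1  <=>  p0 < start+W
    Ms[[ch]] <- .tricubeMatrix(starts + W / 2, p, config@tricubeHalfwidth)
    winChrom <- c(winChrom, rep(ch, length(starts)))
    winStart <- c(winStart, starts)
    lo <- c(lo, wlo + offset)
    hi <- c(hi, whi + offset)
    offset <- offset + length(p)
  }
  nSnps <- pmax(hi - lo + 1L, 0L)
  emit <- nSnps >= config@minSnpsPerWindow
  M <- if (length(Ms) == 1L) Ms[[1L]] else Matrix::bdiag(Ms)
  list(winChrom = winChrom[emit], winStart = winStart[emit],
       lo = lo[emit], hi = hi[emit], nSnps = nSnps[emit],
       M = M[emit, , drop = FALSE],
       signed = any(polarized %in% TRUE),
       deltaMask = if (any(polarized %in% TRUE)) polarized %in% TRUE else NULL,
       windowSize = W, stepSize = step)
}

## NA-aware window means over the (sorted, global-index) cumulative sums
.windowMeans <- function(v, struct) {
  cs <- cumsum(ifelse(is.na(v), 0, v))
  cn <- cumsum(!is.na(v))
  s <- cs[struct$hi] - ifelse(struct$lo > 1L, cs[struct$lo - 1L], 0)
  k <- cn[struct$hi] - ifelse(struct$lo > 1L, cn[struct$lo - 1L], 0L)
  ifelse(k > 0, s / k, NA_real_)
}

.gprimeAtWindows <- function(g, struct) {
  num <- as.vector(struct$M %*% ifelse(is.na(g), 0, g))
  den <- as.vector(struct$M %*% as.numeric(!is.na(g)))
  ifelse(den > 0, num / den, NA_real_)
}

## window-level values of the three scan statistics from raw depth vectors
.scanValues <- function(aRef, aAlt, bRef, bAlt, struct) {
  iA <- aAlt / (aRef + aAlt)
  iB <- bAlt / (bRef + bAlt)
  d <- iA - iB
  dv <- if (struct$signed) ifelse(struct$deltaMask, d, NA_real_) else abs(d)
  ed4 <- 4 * d^4
  g <- gStatistic(aRef, aAlt, bRef, bAlt)
  list(delta = .windowMeans(dv, struct),
       gprime = .gprimeAtWindows(g, struct),
       ed4 = .windowMeans(ed4, struct))
}

#' Sliding-window smoothing of the per-SNP statistics
#'
#' Averages the per-SNP statistics in sliding windows (1 Mb wide, advancing
#' in 100 kb steps by default), anchored at coordinate 0 of each chromosome.
#' A SNP at 1-based position `pos` belongs to the window `[start, end)` when
#' `pos - 1` falls in that 0-based half-open interval. The reported window
#' `gprime` is the tricube-weighted mean of G evaluated at the window
#' midpoint with the configured kernel half-width, so that G-prime and the
#' window means share one genomic grid.
#'
#' When any site is polarized, `meanDelta` is the signed Delta-SNP-index
#' averaged over polarized sites only; otherwise it averages `|Delta|` over
#' all sites.
#'
#' @param stats sorted per-SNP statistics from [computeSnpStats()].
#' @param config a [ScanConfig-class].
#' @return `GRanges` of emitted windows (1-based inclusive coordinates,
#'   width = `windowSize`), with metadata columns `nSnps`, `meanDelta`,
#'   `meanG`, `gprime`, `meanEd4`. Windows with fewer than
#'   `minSnpsPerWindow` SNPs are omitted. `metadata()` carries the config.
#' @export
windowScan <- function(stats, config = scanConfig()) {
  pos <- BiocGenerics::start(stats)
  chrom <- as.character(GenomeInfoDb::seqnames(stats))
  struct <- .scanStructure(pos, chrom, GenomeInfoDb::seqlengths(stats),
                           config, S4Vectors::mcols(stats)$polarized)
  m <- S4Vectors::mcols(stats)
  d <- m$delta
  dv <- if (struct$signed) ifelse(struct$deltaMask, d, NA_real_) else abs(d)
  gr <- GenomicRanges::GRanges(
    seqnames = struct$winChrom,
    ranges = IRanges::IRanges(start = struct$winStart + 1,
                              width = struct$windowSize))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(stats)
  suppressWarnings(GenomeInfoDb::seqlengths(gr) <- GenomeInfoDb::seqlengths(stats))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    nSnps = struct$nSnps,
    meanDelta = .windowMeans(dv, struct),
    meanG = .windowMeans(m$g, struct),
    gprime = .gprimeAtWindows(m$g, struct),
    meanEd4 = .windowMeans(m$ed4, struct))
  S4Vectors::metadata(gr) <- list(config = config, signed = struct$signed)
  gr
}

## approximate-uniform reservoir used only above the exactness cap
.reservoirAdd <- function(res, vals) {
  vals <- vals[!is.na(vals)]
  nv <- length(vals)
  if (!nv) return(res)
  if (res$seen < res$size) {
    take <- min(res$size - res$seen, nv)
    res$buf[res$seen + seq_len(take)] <- vals[seq_len(take)]
    res$seen <- res$seen + take
    vals <- vals[-seq_len(take)]
    nv <- nv - take
  }
  if (nv) {
    t <- res$seen + seq_len(nv)
    keep <- stats::runif(nv) < res$size / t
    if (any(keep))
      res$buf[sample.int(res$size, sum(keep), replace = TRUE)] <- vals[keep]
    res$seen <- res$seen + nv
  }
  res
}

#' Empirical significance thresholds by Monte-Carlo permutation of bulk labels
#'
#' Recomputes the full smoothing pipeline (per-SNP statistics, window means,
#' window G-prime) on `nPermutations` bulk-label permutations of the input
#' sites and takes, per statistic, the requested genome-wide quantiles of
#' the pooled null window values.
#'
#' Two permutation schemes are available. The default, `"reads"`, pools each
#' site's reads and randomly re-partitions them between the two bulks,
#' preserving each bulk's total depth at the site (a hypergeometric draw):
#' this is an exchangeable null for all three statistics. `"pairSwap"` swaps
#' each site's two bulk depth pairs with probability 1/2: it preserves the
#' per-site depth pairs exactly but leaves the 2x2 table (up to row order)
#' unchanged, so G and ED are invariant under it and only the Delta null is
#' informative; it is provided for degenerate-null diagnostics.
#'
#' With a fixed `seed` in the config the result is bit-reproducible. When
#' `nPermutations * windows` exceeds `maxNullValues` the null values are not
#' materialized; a fixed-size uniform reservoir subsample feeds the
#' quantiles instead.
#'
#' @param x a depth-filtered [BulkSnpSet-class] (sorted).
#' @param config a [ScanConfig-class]; `seed`, `nPermutations`, `levels`,
#'   `permScheme` and `pool` are taken from it.
#' @param statistics which statistics to compute thresholds for.
#' @return A [ThresholdSet-class].
#' @export
permutationThresholds <- function(x, config = scanConfig(),
                                  statistics = c("delta", "gprime", "ed4")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  pos <- BiocGenerics::start(x)
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  struct <- .scanStructure(pos, chrom, GenomeInfoDb::seqlengths(x),
                           config, isPolarized(x))
  adRef <- refDepth(x)
  adAlt <- altDepth(x)
  aRef <- as.numeric(adRef[, 1L]); aAlt <- as.numeric(adAlt[, 1L])
  bRef <- as.numeric(adRef[, 2L]); bAlt <- as.numeric(adAlt[, 2L])
  n <- length(pos)
  nPerm <- config@nPermutations

  units <- if (config@pool == "genome") rep("genome", length(struct$lo))
           else struct$winChrom
  unitNames <- unique(units)
  unitIdx <- lapply(unitNames, function(u) which(units == u))
  names(unitIdx) <- unitNames

  exact <- (length(struct$lo) * as.numeric(nPerm)) <= config@maxNullValues
  if (exact) {
    store <- stats::setNames(lapply(statistics, function(s)
      matrix(NA_real_, nrow = length(struct$lo), ncol = nPerm)), statistics)
  } else {
    resSize <- max(1000L,
                   as.integer(config@maxNullValues / (length(statistics) *
                                                      length(unitNames))))
    store <- stats::setNames(lapply(statistics, function(s)
      stats::setNames(lapply(unitNames, function(u)
        list(buf = numeric(resSize), seen = 0L, size = resSize)), unitNames)),
      statistics)
  }

  set.seed(config@seed)
  altTot <- aAlt + bAlt
  refTot <- aRef + bRef
  depthA <- aRef + aAlt
  for (p in seq_len(nPerm)) {
    if (config@permScheme == "reads") {
      pAAlt <- stats::rhyper(n, m = altTot, n = refTot, k = depthA)
      pARef <- depthA - pAAlt
      pBAlt <- altTot - pAAlt
      pBRef <- refTot - pARef
    } else {
      sw <- stats::runif(n) < 0.5
      pARef <- ifelse(sw, bRef, aRef); pAAlt <- ifelse(sw, bAlt, aAlt)
      pBRef <- ifelse(sw, aRef, bRef); pBAlt <- ifelse(sw, aAlt, bAlt)
    }
    vals <- .scanValues(pARef, pAAlt, pBRef, pBAlt, struct)
    for (s in statistics) {
      if (exact) store[[s]][, p] <- vals[[s]]
      else for (u in unitNames)
        store[[s]][[u]] <- .reservoirAdd(store[[s]][[u]], vals[[s]][unitIdx[[u]]])
    }
  }

  thresholds <- lapply(unitNames, function(u) {
    m <- matrix(NA_real_, nrow = length(statistics), ncol = length(config@levels),
                dimnames = list(statistics, as.character(config@levels)))
    for (s in statistics) {
      nullVals <- if (exact) store[[s]][unitIdx[[u]], , drop = FALSE]
                  else store[[s]][[u]]$buf[seq_len(min(store[[s]][[u]]$seen,
                                                       store[[s]][[u]]$size))]
      m[s, ] <- stats::quantile(nullVals, probs = config@levels,
                                na.rm = TRUE, names = FALSE)
    }
    m
  })
  names(thresholds) <- unitNames
  methods::new("ThresholdSet",
               thresholds = thresholds,
               levels = config@levels,
               seed = config@seed,
               nPermutations = nPerm,
               permScheme = config@permScheme,
               pool = config@pool)
}

#' Call candidate QTL intervals from significant windows
#'
#' Windows whose value meets or exceeds the threshold for the chosen
#' statistic and level are merged when they overlap or leave a gap of at
#' most one step; each merged interval reports the peak window (maximum
#' value) midpoint and value. Interval coordinates are 1-based inclusive.
#'
#' @param windows output of [windowScan()].
#' @param thresholds a [ThresholdSet-class].
#' @param statistic `"delta"`, `"gprime"` or `"ed4"` (anything else is an
#'   error).
#' @param level confidence level present in `thresholds`.
#' @param step merge gap in bp; defaults to the step recorded in
#'   `metadata(windows)$config`.
#' @return `GRanges` of candidate intervals with metadata columns
#'   `statistic`, `level`, `threshold`, `peakPos`, `peakValue`, `nWindows`.
#' @export
callIntervals <- function(windows, thresholds, statistic, level = 0.95,
                          step = NULL) {
  colMap <- c(delta = "meanDelta", gprime = "gprime", ed4 = "meanEd4")
  if (length(statistic) != 1L || !statistic %in% names(colMap))
    stop("unknown statistic '", paste(statistic, collapse = ","), "'")
  if (is.null(step)) {
    cfg <- S4Vectors::metadata(windows)$config
    if (is.null(cfg)) stop("no step given and windows carry no config")
    step <- cfg@stepSize
  }
  vals <- S4Vectors::mcols(windows)[[colMap[[statistic]]]]
  chrom <- as.character(GenomeInfoDb::seqnames(windows))
  thr <- vapply(chrom, function(ch)
    thresholdFor(thresholds, statistic, level, chrom = ch), numeric(1))
  sig <- !is.na(vals) & vals >= thr
  sel <- windows[sig]
  merged <- GenomicRanges::reduce(GenomicRanges::granges(sel),
                                  min.gapwidth = step + 1)
  if (!length(merged)) {
    S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
      statistic = character(0), level = numeric(0), threshold = numeric(0),
      peakPos = numeric(0), peakValue = numeric(0), nWindows = integer(0))
    return(merged)
  }
  ov <- GenomicRanges::findOverlaps(merged, sel)
  selVals <- vals[sig]
  peakPos <- numeric(length(merged))
  peakValue <- numeric(length(merged))
  nWin <- integer(length(merged))
  for (i in seq_along(merged)) {
    j <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]
    nWin[i] <- length(j)
    k <- j[which.max(selVals[j])]
    peakValue[i] <- selVals[k]
    peakPos[i] <- floor((BiocGenerics::start(sel)[k] +
                         BiocGenerics::end(sel)[k]) / 2)
  }
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    statistic = statistic, level = level,
    threshold = vapply(as.character(GenomeInfoDb::seqnames(merged)),
                       function(ch) thresholdFor(thresholds, statistic, level,
                                                 chrom = ch), numeric(1)),
    peakPos = peakPos, peakValue = peakValue, nWindows = nWin)
  merged
}

#' Run the full genome scan on a BulkSnpSet
#'
#' Convenience wrapper: per-SNP statistics, sliding-window smoothing,
#' permutation thresholds and interval calling for every requested statistic
#' at every configured level.
#'
#' @param x a depth-filtered [BulkSnpSet-class].
#' @param config a [ScanConfig-class].
#' @param highBulk which bulk is the high-trait bulk (`"A"` or `"B"`).
#' @param statistics statistics to scan.
#' @param lowIndex passed to [computeSnpStats()].
#' @return list with elements `snpStats` (GRanges), `windows` (GRanges),
#'   `thresholds` ([ThresholdSet-class]) and `intervals` (GRanges, all
#'   statistic/level combinations concatenated).
#' @export
bsaScan <- function(x, config = scanConfig(), highBulk = "A",
                    statistics = c("delta", "gprime", "ed4"),
                    lowIndex = "bulk") {
  snpStats <- computeSnpStats(x, highBulk = highBulk, lowIndex = lowIndex)
  windows <- windowScan(snpStats, config)
  thresholds <- permutationThresholds(x, config, statistics = statistics)
  pieces <- list()
  for (s in statistics)
    for (lv in config@levels)
      pieces[[paste(s, lv)]] <- callIntervals(windows, thresholds, s, lv)
  intervals <- if (length(pieces)) suppressWarnings(do.call(c, unname(pieces)))
               else GenomicRanges::GRanges()
  list(snpStats = snpStats, windows = windows, thresholds = thresholds,
       intervals = intervals)
}

#' Manhattan-style scan panels
#'
#' One panel per chromosome: the smoothed statistic along the chromosome
#' with horizontal lines at the empirical thresholds (95% blue, higher
#' levels grey), mirroring the usual BSA scan figures.
#'
#' @param windows output of [windowScan()].
#' @param thresholds optional [ThresholdSet-class] (genome pooling).
#' @param statistic `"delta"`, `"gprime"` or `"ed4"`.
#' @return a `ggplot` object.
#' @export
plotScan <- function(windows, thresholds = NULL, statistic = "gprime") {
  colMap <- c(delta = "meanDelta", gprime = "gprime", ed4 = "meanEd4")
  labMap <- c(delta = "Delta SNP-index", gprime = "G'", ed4 = "ED4")
  if (!statistic %in% names(colMap)) stop("unknown statistic")
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(windows)),
    mid = (BiocGenerics::start(windows) + BiocGenerics::end(windows)) / 2,
    value = S4Vectors::mcols(windows)[[colMap[[statistic]]]])
  df$mb <- df$mid / 1e6
  p <- ggplot2::ggplot(df, ggplot2::aes(x = mb, y = value)) +
    ggplot2::geom_line(colour = "red3", linewidth = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = labMap[[statistic]]) +
    ggplot2::theme_bw()
  if (!is.null(thresholds)) {
    for (lv in thresholds@levels) {
      thr <- thresholdFor(thresholds, statistic, lv)
      p <- p + ggplot2::geom_hline(yintercept = thr,
                                   colour = if (lv <= 0.95) "steelblue" else "grey40",
                                   linetype = "dashed")
    }
  }
  p
}

#' Export window, threshold and interval tables
#'
#' `exportWindowTable()` writes the window scan as TSV (`chrom`, `start`,
#' `end` 1-based inclusive, `n_snps`, `mean_delta`, `mean_g`, `gprime`,
#' `mean_ed4`); `exportThresholdTable()` writes one row per pooling unit x
#' statistic x level; `exportIntervalsBed()` writes candidate intervals as
#' BED (0-based half-open, score = peak value).
#'
#' @param windows,thresholds,intervals scan outputs.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportWindowTable <- function(windows, path) {
  m <- S4Vectors::mcols(windows)
  fmt <- function(v) ifelse(is.na(v), ".", format(v, digits = 10, trim = TRUE))
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(windows)),
    start = BiocGenerics::start(windows),
    end = BiocGenerics::end(windows),
    n_snps = m$nSnps,
    mean_delta = fmt(m$meanDelta),
    mean_g = fmt(m$meanG),
    gprime = fmt(m$gprime),
    mean_ed4 = fmt(m$meanEd4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWindowTable
#' @export
exportThresholdTable <- function(thresholds, path) {
  rows <- list()
  for (u in names(thresholds@thresholds)) {
    m <- thresholds@thresholds[[u]]
    for (s in rownames(m))
      rows[[length(rows) + 1L]] <- data.frame(
        pool = u, statistic = s, level = as.numeric(colnames(m)),
        threshold = m[s, ])
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname exportWindowTable
#' @export
exportIntervalsBed <- function(intervals, path) {
  m <- S4Vectors::mcols(intervals)
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(intervals)),
    start = BiocGenerics::start(intervals) - 1L,   # BED is 0-based half-open
    end = BiocGenerics::end(intervals),
    name = if (length(intervals)) paste0(m$statistic, "_", m$level) else character(0),
    score = if (length(intervals)) m$peakValue else numeric(0),
    strand = rep(".", length(intervals)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
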