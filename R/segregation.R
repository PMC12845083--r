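#' @include AllClasses.R
NULL

#' Chi-square goodness-of-fit test of a Mendelian segregation ratio
#'
#' Pearson chi-square test of a two-class phenotype count against an
#' expected `a:b` ratio, as used to decide how many duplicate genes control
#' a trait class. Expected counts are `total * ratio / sum(ratio)`; the
#' statistic is `sum((O - E)^2 / E)` with 1 degree of freedom and *no*
#' continuity correction (classical segregation tables are computed without
#' it), and the p-value is the upper chi-square tail.
#'
#' @param observed integer vector of length 2: counts of the class of
#'   interest and its complement.
#' @param ratio positive numeric vector of length 2: expected proportions,
#'   e.g. `c(1, 3)` for a 1:3 ratio.
#' @return one-row data.frame: `obs1`, `obs2`, `ratio`, `exp1`, `exp2`,
#'   `chi2`, `df`, `p`.
#' @examples
#' chiSquareRatio(c(23, 52), c(1, 3))   # chi2 ~ 1.284
#' chiSquareRatio(c(25, 75), c(1, 3))   # perfect fit: chi2 = 0, p = 1
#' @export
chiSquareRatio <- function(observed, ratio) {
  stopifnot(length(observed) == 2L, length(ratio) == 2L)
  if (any(ratio <= 0)) stop("ratio entries must be positive")
  total <- sum(observed)
  if (total <= 0) stop("observed total must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) stop("expected count of zero")
  chi2 <- sum((observed - expected)^2 / expected)
  data.frame(obs1 = observed[1L], obs2 = observed[2L],
             ratio = paste0(ratio[1L], ":", ratio[2L]),
             exp1 = expected[1L], exp2 = expected[2L],
             chi2 = chi2, df = 1L,
             p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Scan duplicate-gene segregation models
#'
#' Tests the observed two-class counts against the Mendelian ratios expected
#' when the class of interest requires recessive homozygosity at `n`
#' duplicate loci, `1 : (4^n - 1)` for `n = 1..maxGenes` (15:1, 63:1, 255:1
#' F2 ratios for 2, 3, 4 duplicate recessive genes), or the mirrored
#' `(4^n - 1) : 1` ratios when the class of interest is dominant.
#'
#' @param observed counts `(class of interest, complement)`.
#' @param maxGenes test 1..`maxGenes` genes (`<= 8`).
#' @param recessiveClass is the class of interest the recessive class?
#' @return data.frame with one row per gene number (`nGenes` column plus the
#'   [chiSquareRatio()] columns).
#' @examples
#' modelScan(c(1, 21), maxGenes = 4)           # white : pink style counts
#' modelScan(c(23, 52), maxGenes = 2, recessiveClass = FALSE)
#' @export
modelScan <- function(observed, maxGenes = 4L, recessiveClass = TRUE) {
  stopifnot(maxGenes >= 1L, maxGenes <= 8L)
  rows <- lapply(seq_len(maxGenes), function(n) {
    k <- 4^n - 1
    ratio <- if (recessiveClass) c(1, k) else c(k, 1)
    cbind(nGenes = n, chiSquareRatio(observed, ratio))
  })
  do.call(rbind, rows)
}

#' Segregation report for several phenotype contrasts
#'
#' Runs [modelScan()] for each labelled count pair and assembles the classic
#' segregation-table layout: phenotype contrast, gene number, ratio,
#' expected counts, chi-square, the 5% critical value for 1 df, and p.
#'
#' @param counts data.frame with columns `label`, `a` (class of interest),
#'   `b` (complement), and optionally `class` (`"recessive"`/`"dominant"`,
#'   default recessive).
#' @param maxGenes models tested per contrast.
#' @return data.frame in table layout.
#' @export
segregationReport <- function(counts, maxGenes = 4L) {
  stopifnot(all(c("label", "a", "b") %in% colnames(counts)))
  cls <- if ("class" %in% colnames(counts)) counts$class
         else rep("recessive", nrow(counts))
  crit <- stats::qchisq(0.95, df = 1L)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    ms <- modelScan(c(counts$a[i], counts$b[i]), maxGenes = maxGenes,
                    recessiveClass = cls[i] == "recessive")
    data.frame(phenotype = counts$label[i],
               n_genes = ms$nGenes,
               observed = paste0(ms$obs1, ":", ms$obs2),
               ratio = ms$ratio,
               expected = sprintf("%.2f:%.2f", ms$exp1, ms$exp2),
               chi2 = ms$chi2,
               chi2_crit_0.05 = crit,
               p = ms$p)
  })
  do.call(rbind, rows)
}
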