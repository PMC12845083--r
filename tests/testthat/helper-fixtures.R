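# Fixture builders and independent oracles shared across the test files.

# Write a small VCF text fixture. `records` is a character vector of
# body lines (tab-separated CHROM..sample fields).
writeTestVcf <- function(records, samples = c("bulkA", "bulkB"),
                         contigs = c(Chr01 = 2e6),
                         path = tempfile(fileext = ".vcf")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Independent brute-force G oracle: build the 2x2 table, compute expected
# counts cell by cell from the marginals, and sum the log-likelihood terms
# in an explicit double loop.
bruteForceG <- function(aRef, aAlt, bRef, bAlt) {
  obs <- matrix(c(aRef, aAlt, bRef, bAlt), nrow = 2, byrow = TRUE)
  tot <- sum(obs)
  if (tot == 0) return(NA_real_)
  g <- 0
  for (i in 1:2) for (j in 1:2) {
    e <- sum(obs[i, ]) * sum(obs[, j]) / tot
    if (obs[i, j] > 0) g <- g + obs[i, j] * log(obs[i, j] / e)
  }
  2 * g
}

# Naive O(n^2) tricube-weighted mean oracle for G-prime.
naiveTricube <- function(pos, vals, halfwidth, evalPos = pos) {
  vapply(evalPos, function(p) {
    w <- vapply(pos, function(q) {
      u <- abs(q - p) / halfwidth
      if (u <= 1) (1 - u^3)^3 else 0
    }, numeric(1))
    keep <- !is.na(vals) & w > 0
    if (!any(keep)) return(NA_real_)
    sum(w[keep] * vals[keep]) / sum(w[keep])
  }, numeric(1))
}

# Forward gamete-level Monte-Carlo of selfing to fixation at two loci with
# per-meiosis recombination fraction r; returns the fraction of fixed lines
# recombinant between the loci. Independent of the closed form under test.
forwardRilRecomb <- function(r, nLines = 1e5, generations = 25L) {
  # haplotype encoded as 2 bits: bit 1 = allele at locus 1, bit 2 = locus 2
  a1 <- rep(0L, nLines); b1 <- rep(0L, nLines)   # haplotype 1: 0-0
  a2 <- rep(1L, nLines); b2 <- rep(1L, nLines)   # haplotype 2: 1-1
  gamete <- function() {
    pick <- stats::rbinom(nLines, 1L, 0.5) == 1L  # parent haplotype at locus 1
    rec <- stats::rbinom(nLines, 1L, r) == 1L
    ga <- ifelse(pick, a2, a1)
    pick2 <- xor(pick, rec)
    gb <- ifelse(pick2, b2, b1)
    list(a = ga, b = gb)
  }
  for (g in seq_len(generations)) {
    g1 <- gamete(); g2 <- gamete()
    a1 <- g1$a; b1 <- g1$b; a2 <- g2$a; b2 <- g2$b
  }
  mean(a1 != b1)
}
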