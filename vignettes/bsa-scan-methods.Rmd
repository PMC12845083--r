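---
title: "Bulked-segregant genome scans: models, calibration and design choices"
author: "BSAscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bulked-segregant genome scans: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BSAscan)
```

## The measurement model

BSA-seq compares two DNA pools of phenotypically extreme individuals. At a
biallelic site, each bulk contributes a pair of read counts
(reference, alternate); the alternate-read fraction (the SNP-index)
estimates the bulk's allele frequency. Away from any causal locus both bulks
descend from the same segregating population and their frequencies share an
expectation, so the ΔSNP-index (high-trait minus low-trait bulk) is centred
at zero. Close to a causal locus, selection of extreme phenotypes drives the
bulks' frequencies apart in proportion to linkage, so |Δ| rises towards 1.

Three per-SNP statistics are computed on the same 2×2 (bulk × allele) read
count table:

* ΔSNP-index, the frequency difference itself (signed when sites are
  polarized, |Δ| otherwise);
* the G statistic, the log-likelihood-ratio of the table,
  `G = 2 Σ n ln(n/n̂)` with expectations from the marginals — it weighs the
  same contrast by the available depth, with the conventions
  `0·ln(0/x) = 0` and zero-margin tables giving G = 0;
* ED⁴, where `ED = √(2 (f_A − f_B)²)` is the Euclidean distance between the
  bulks' frequency vectors over both allele axes. The fourth power
  suppresses the small background contrasts that read sampling alone
  produces while leaving strong signals essentially untouched. Note
  `ED = √2·|Δ|` at a biallelic site: the raw scales differ by √2 but the
  two scans rank loci identically; thresholds are computed on each
  statistic's own scale, so the factor cancels in inference.

Sites with fewer than 10 reads in *either* bulk are discarded before any
statistic is computed (a strict `< 10` rule: totals of exactly 10 survive).
Undefined values (zero depth) propagate as `NA`, never as zero — a zero
would masquerade as evidence of no contrast.

## Polarization

The sign of Δ is only meaningful if the alternate allele consistently tags
one parent. When parental genotypes are available, every site is reoriented
so that the alternate allele is the high-trait parent's homozygous allele;
sites where a parent call is heterozygous, missing, or where the parents do
not carry opposite homozygous alleles are flagged unpolarizable and are
excluded from the signed Δ scan while remaining in the |Δ|, G and ED scans.
Without parents the scan runs on |Δ| throughout. G and ED are invariant to
orientation, so polarization never affects them.

## Smoothing

Individual SNP statistics are noisy; linkage makes neighbouring sites carry
shared signal. Two smoothers are used:

* sliding windows, 1 Mb wide advancing in 100 kb steps, anchored at
  coordinate 0 of every chromosome. Window membership uses 0-based
  half-open arithmetic (a 1-based SNP position `pos` is in `[start, end)`
  iff `pos − 1` is), and emitted rows report 1-based inclusive bounds.
  Windows with fewer SNPs than `minSnpsPerWindow` (default 1, i.e. empty
  windows) are not emitted;
* a tricube kernel, `w(d) = (1 − (|d|/h)³)³` for `|d| ≤ h`, for G′. The
  per-SNP G′ is the tricube-weighted mean of G over all SNPs within `h` on
  the same chromosome. The window-level G′ reported by the scan is the same
  weighted mean evaluated at window midpoints, so that all three statistics
  share one genomic grid; the half-width defaults to half the window size
  (500 kb), giving G′ the same 1 Mb footprint as the window means. The
  half-width is exposed (`tricubeHalfwidth`) because the appropriate
  bandwidth is a genuine analysis choice, not a constant of the method.

## Permutation thresholds

Significance is assessed against an empirical null constructed by
Monte-Carlo permutation of bulk labels at each site, re-running the entire
smoothing pipeline per replicate, and pooling the null window values
genome-wide; the 95% and 99% thresholds are quantiles of that pool. Both
levels are computed by default and drawn on the scan plots. A
per-chromosome pooling option exists for genomes with heterogeneous marker
density.

What "permuting bulk labels" means at a single site deserves care. Swapping
the site's two depth *pairs* between bulks preserves the observed pairs but
maps the 2×2 table onto itself up to row order — G and ED are invariant
under it, so that scheme (provided as `permScheme = "pairSwap"` for
degenerate-null diagnostics) yields an informative null only for Δ. The
default scheme (`"reads"`) instead pools the site's reads and re-partitions
them randomly between the bulks, preserving each bulk's total depth (a
hypergeometric draw). Under the hypothesis that reads are exchangeable
between bulks this is the exact conditional null for all three statistics,
and one replicate is one draw from it; with a fixed seed the whole
procedure is bit-reproducible. The default replicate count is 100,000; the
examples and tests in this package use a few hundred, which is ample for a
95% pooled quantile over hundreds of windows.

When `nPermutations × windows` exceeds `maxNullValues` (default 10⁷) the
null values are not materialized; a fixed-size uniform reservoir subsample
(approximate Algorithm R, batched) feeds the quantiles instead. Below the
cap quantiles are exact.

### What the thresholds do and do not control

The permutation null conditions on the observed per-site coverage and
models *read sampling* exchangeability. On data whose only noise is read
sampling — e.g. both bulks binomial around a common frequency — the 95%
threshold is well calibrated: the package's tests measure a pooled window
exceedance of 4–5% across 20 replicate simulations for each statistic.

Real bulks carry a second noise source: the finite number of lines pooled.
With 20 lines per bulk the bulk allele frequency at any locus has a
standard deviation of about `√(0.25/20) ≈ 0.11` around 0.5, and because a
line's genome is locally constant this noise is strongly autocorrelated
along the chromosome. No site-local permutation of reads or labels can
represent it, so on fully simulated null designs (bulks of 20 lines, no
QTL) the windowed statistics exceed the read-sampling threshold far more
often than the nominal 5% — the package's power analysis reports this
honestly rather than hiding it. In practice this matters for weak signals:
strong QTL contrasts (|Δ| near 1) dwarf both noise sources, which is why
interval recovery in the tests is unaffected. Users scanning for small
effects should treat the permutation threshold as a lower bound on the
evidence required and lean on the peak structure, replication, or larger
bulks.

## Interval calling

Windows at or above the threshold for a chosen statistic and level are
merged when they overlap or leave a gap of at most one step; each merged
interval reports its peak window's midpoint and value. With the default
overlapping windows (width 10× step) a single significant window already
spans 1 Mb, so reported intervals are conservative supersets of the causal
region; the peak midpoint is the better point estimate.

## The simulator

The simulator generates data with exactly the structure the scan assumes,
plus ground truth for calibration and power studies. Design choices:

* **RIL genetics.** Lines are products of repeated selfing. A line's
  high-allele indicator along a chromosome is simulated as a Markov chain
  over the marker grid with switch probability `R = 2r/(1 + 2r)` between
  adjacent markers, the classical recombinant fraction of selfing-derived
  RILs, with `r` from the Haldane map function (no interference —
  interference changes local clustering of crossovers, not the
  frequency-level behaviour the scan statistics consume).
* **Residual heterozygosity** is modelled per locus, independently, with
  probability `(1/2)^(generation−1)` (F5 default: 1/16); a heterozygous
  locus contributes frequency 1/2 to its line. This ignores the tract
  structure of real residual heterozygosity, which is adequate for
  frequency-level statistics but understates the spatial correlation of
  the heterozygous stretches.
* **Selection** into bulks acts at the line level: a high-bulk line carries
  the high allele at the QTL with probability `effect` (1 = complete
  selection, as when bulks are built from lines whose phenotype was stable
  across seasons); a low-bulk line with probability `1 − effect`. This
  emulates phenotype-based selection without an explicit phenotype model;
  `effect` values in (0.5, 1) stand in for misclassification, incomplete
  penetrance or minor-locus contributions.
* **Read sampling.** Depth per site per bulk is Poisson (or fixed) around
  `meanDepth`; alternate reads are binomial in the true bulk frequency.
  No sequencing error or mapping bias is modelled: those processes mostly
  perturb both bulks symmetrically and would largely cancel in the
  contrasts, but data with allele-specific mapping artefacts will violate
  the simulator's assumptions.
* **Defaults** mirror the RIL design the scan targets: two bulks of 20 F5
  lines, ~40× per bulk, markers every 25 kb on a 25 Mb chromosome, and a
  map density of 2 cM/Mb — genome-wide averages in large-genome legumes
  are nearer 1 cM/Mb, but QTL mapping resolution is set by the gene-rich,
  recombining regions, for which 2 cM/Mb is a reasonable middle value.

One QTL per chromosome is supported (the line-level Markov chain is
simulated conditionally outward from the QTL marker); multi-QTL designs are
built from multiple chromosomes.

The test suite checks the simulator against independent oracles: the RIL
recombinant fraction against a 10⁵-line forward simulation of selfing to
fixation, and the recorded truth frequencies against observed indices at
10⁵× depth.

## Numerical choices

* G is computed in double precision (32-bit marginal products overflow at
  ~10⁵× depth) and clamped at 0 against rounding residue.
* Window means and kernel smooths are NA-aware: undefined per-SNP values
  are excluded from both numerator and denominator, and a window with no
  usable value reports `NA`, never 0.
* Quantiles use R's default type-7 definition.
* Permutation replicates reuse a precomputed scan structure (window
  membership and kernel weights depend only on positions), so each
  replicate costs a few vectorized operations and two sparse
  matrix-vector products; 500 permutations on 2,000 SNPs take well under a
  second.
* Problem sizes in the tests and acceptance script (2,000-SNP nulls,
  500 permutations, 20 replicate seeds; 1,000-marker QTL designs, 200
  permutations) were chosen as the smallest sizes at which the calibration
  and recovery checks have comfortable Monte-Carlo margins.

## Segregation-ratio testing

The number of duplicate genes controlling a phenotype class is tested by
Pearson chi-square goodness-of-fit of the observed two-class counts against
`1 : (4ⁿ − 1)` (recessive class of interest) or its mirror, for n = 1..4 by
default, with 1 degree of freedom and no continuity correction — published
segregation tables are computed without it, and the classical printed
values are reproducible only without it. Expected counts are kept at full
precision; one widely printed value (the 1:21 counts against 1:63, printed
as 1.312) is not the exact Pearson value (14/11 = 1.2727…), most likely a
casualty of rounded intermediate expected counts, and this package returns
the exact value.

## Known limitations

* The permutation null does not capture bulk-composition (line-sampling)
  noise; see the calibration section above.
* Indels are excluded by default (`keepIndels` readmits them); the
  statistics are allele-length-agnostic but headline scans are SNP-based.
* Only biallelic sites are used; multiallelic records are dropped, not
  decomposed.
* Genotype likelihoods are ignored: only integer AD counts are consumed,
  so upstream callers' filtering quality directly bounds scan quality.
* Passing the simulator-based tests shows the pipeline recovers loci under
  the stated genetic model; real data add mapping bias, paralogy and
  coverage heterogeneity that the simulator deliberately omits.
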