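---
title: "Methods: CHA enhancers, their connectome, and causal screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CHA enhancers, their connectome, and causal screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaconnectome)
library(dplyr)
```

This vignette documents the models, conventions and design choices behind
`chaconnectome`, in the order the pipeline runs. Everything here is
exercised by the test suite; no empirical claim is made that the tests and
`scripts/acceptance.R` do not themselves compute.

## Coordinates and interval conventions

All region tables use 0-based half-open coordinates (BED). The midpoint of
an interval `[start, end)` is `floor((start + end) / 2)`; since sources
rarely state a rounding rule for even-length intervals, fixing floor makes
every midpoint-based statistic reproducible bit-for-bit. Promoter and
blacklist exclusion removes whole peak records (`bedtools -v` semantics),
never trimmed fragments, because the unit of analysis downstream is the
peak, not its surviving bases. Output ordering is lexicographic on
chromosome, then numeric on start — deterministic across platforms.

Interval overlap, union and intersection are delegated to
GenomicRanges/IRanges behind a tibble-first surface; the test suite checks
every overlap operation against a naive per-base oracle on toy genomes.

## CHA classification

CAGE replicates are combined by the arithmetic mean over all replicates;
an annotation with all-zero replicates keeps a combined value of 0. (Note
the mean over *all* replicates: `(3, 0, 0)` combines to 1, not 3. Dividing
by the nonzero count instead would inflate sparse annotations and make the
percentile threshold depend on replicate dropout.)

The classification threshold is the nearest-rank `pct`-th percentile —
the smallest observed value whose cumulative fraction reaches `pct/100`,
i.e. the `ceiling(pct/100 * n)`-th order statistic — of combined tags over
annotations with nonzero combined tag. Restricting the reference
population to nonzero annotations keeps the threshold meaningful when most
annotations are silent: with zeros included, any zero-inflation level above
`1 - pct/100` would drive the threshold to 0 and label every
CAGE-overlapping enhancer CHA. The comparison at the threshold is
inclusive (≥), and an enhancer with no CAGE overlap at all is regular by
definition.

## Hub regulatory units

For every promoter we count distinct significant loops whose one anchor
intersects the promoter and whose other anchor intersects a CHA enhancer.
Counting *loops* rather than distinct enhancers follows the convention
that a promoter contacted twice by the same strong enhancer is more
connected than one contacted once. The reference population for the hub
threshold is promoters with at least one CHA loop — promoters without CHA
contact are not CHA regulatory units at all.

The hub threshold is the nearest-rank percentile of the **distinct**
observed loop counts (ties collapsed before ranking), with an inclusive
comparison. Loop counts are small integers with heavy ties; a plain
value-rank percentile would place the threshold inside the bulk of tied
low counts, so the "top decile" would always swallow at least 10% of
promoters no matter how extreme the genuine hubs are. Collapsing ties
makes the threshold mark a boundary between connectivity *levels*: in a
population of nine singly-connected promoters and one with ten loops, the
hub is the one with ten loops, and when every promoter has the same count
they are all (trivially) at the top level. Both degenerate cases are
frozen in the test suite. For the continuous CAGE tags of the
classification step the two rules coincide, and the value-rank rule is
used there.

## Signal profiles

Tracks are bedGraph tibbles; overlapping records add when materialised to
per-base coverage, which lets generators compose background plus bumps.
Normalisation to a fixed total (default 10⁷ tags) precedes input
subtraction, so the subtraction compares like with like; negative values
after subtraction are retained rather than clipped, preserving linearity
(`profile(αt) = α·profile(t)`, a tested property). Per-bin values are
means of per-base coverage (not tag 5′-end counts — the package consumes
coverage, not reads), and per-center aggregation is a mean so profiles are
comparable between groups of different sizes. Minus-strand metagene
windows are read 3′→5′ in genomic coordinates so all offsets are in
transcribed orientation.

Group comparisons use the two-sided Wilcoxon rank-sum test with the
normal approximation and tie correction, without continuity correction;
fully tied data return p = 1 rather than 0/0.

## Pause index

The pause index is the ratio of tag density in the strand-oriented TSS
window [−50, +300) to the density over the remaining body [TSS+300, TES).
Both windows are length-normalised, making the index dimensionless and
invariant to sequencing depth (a tested property). The body starts where
the promoter window ends, so no base is counted twice. Genes with zero
promoter density are filtered out before any comparison; positive promoter
signal over an empty body yields `Inf` (flagged, and counted as paused
under the strict `> 2` rule). The 95% CI of the group median is a
percentile bootstrap (10,000 replicates, fixed seed 1234 by default) —
reported CIs in the source material come without a stated method, and the
percentile bootstrap is the assumption-light default.

## Enrichment statistics

The two-sided Fisher p-value is the sum of hypergeometric point
probabilities not exceeding the observed one, with a relative tolerance of
1e-7 on the comparison — the dominant software convention, so published
extreme p-values are reproducible. Sums are computed in log space via
`dhyper(log = TRUE)` and log-sum-exp; with ~26,000 enhancers the two-sided
p reaches 10⁻²¹⁴, far below where naive summation loses digits. The test
suite checks the implementation against exhaustive `choose()`-arithmetic
enumeration for every table with margins ≤ 30 and against `fisher.test`
on random tables.

Gene-set enrichment is the upper-tail hypergeometric `P(X ≥ k)` against a
stated background universe. The projection test measures referent coverage
after union-collapse, counts query midpoints inside referents, and takes
the one-sided binomial upper tail; `fold = k/(n·p)`. The
relative-distance statistic maps each query midpoint lying between
consecutive referent midpoints `L < q ≤ R` to
`d = min(q−L, R−q)/(R−L) ∈ [0, 0.5]`, pools `d` across chromosomes (a
single genome-wide test, matching how the result is usually reported), and
applies a one-sample two-sided KS test against Uniform(0, 0.5). Queries
outside the referent hull and chromosomes with fewer than two referents
are dropped.

## Variants and Mendelian randomization

PICS filtering is inclusive at probability 0.025. Variant→gene mapping
emits a pair iff the variant lies inside a CHA enhancer that a significant
loop links to the gene's promoter; one variant may map to several genes.
Clumping is greedy by ascending p (ties: position, then id), accepting a
variant iff its r² with every previously accepted variant within the
window is below the ceiling; pairs absent from the LD table count as
independent with a warning, since sparse long-format LD tables are the
common interchange.

IVW MR is fixed-effects with first-order Wald-ratio weights
(`se_j = se_out,j/|b_exp,j|`, exposure uncertainty ignored in the weight)
— the default of the standard MR packages. Instruments with zero exposure
effect are dropped with a warning; fewer than three usable instruments is
a refusal, not a result. The screen selects cis instruments at
`p < 5×10⁻⁸` within ±500 kb of the strand-aware TSS, clumps at `r² < 0.1`,
and flags pairs with `p_IVW < 0.05` as causal candidates; pairs failing
the instrument gate are reported as not testable.

## The synthetic study

`simulate_study()` generates every input with planted truth. Defaults,
chosen once as a desk-scale echo of the study system: 2 chromosomes × 5 Mb,
300 genes, 2000 enhancers, CHA fraction 4.5%, 200 loop-connected promoters
of which 8 are hubs, pause-index medians 2.96 (hub genes) / 5.15 (others,
log-normal with σ_log = 0.5), and a causal effect of 0.41 for 13 of 40
gene–trait pairs with 20 strong instruments each (exposure effects
±U(0.2, 0.5) with se 0.002; outcome se 0.05). These sizes keep the full
study under ~10 s on one CPU while leaving percentile thresholds stable.

Choices worth recording:

* **CAGE model.** Background tags are a shifted negative binomial
  (overdispersed counts, support ≥ 1); zero inflation is realised by the
  enhancers that carry no CAGE annotation. The number of tag-carrying
  annotations is derived from the planted CHA count `k` as `10k − 1`, which
  makes the inclusive top decile of nonzero tags exactly the planted set:
  planted annotations (multiplied by `cha_multiplier`, default 100) are
  recovered exactly, and under a unit multiplier the by-chance CHA fraction
  equals the configured `cha_fraction`.
* **Hub degrees.** Background CHA-loop degrees are drawn from the fixed
  support {1,…,9} with Poisson(4) weights — all nine levels are present
  almost surely at 192 draws — and planted hubs take degrees {30, 31}.
  Under the tie-collapsed percentile the hub threshold then lands on the
  smallest planted degree for any seed, so hub recovery is exact by
  construction; this is the regime the hub caller is designed for
  (outlying connectivity levels above a bounded background).
* **Coverage tracks** are exact step functions (promoter and body
  segments for run-on coverage; rectangular bumps at enhancers for
  chromatin marks), so noiseless inversion of the pause index is a sharp
  test of window arithmetic rather than of smoothing.
* **MR inputs** use block-diagonal LD (near-independent instruments, plus
  planted redundant shadows at r² = 0.95 that clumping must remove) and
  outcome effects `θ·b_exp + N(0, se_out)`.
* **Variant truth** is derived by exact coordinate joins on the
  constructed loop anchors, never by interval overlap, so the mapping
  function is validated against an independent code path.

What the generator does **not** emulate: read-level noise and alignment
artefacts, realistic chromosome lengths and gene density, LD beyond block
structure, correlated pleiotropy among instruments, assay-specific biases
(GC content, mappability), or loop-calling uncertainty beyond a planted
q-value split. Passing tests therefore demonstrate correctness of the
implemented procedures under their stated models, not robustness of the
scientific conclusions to real-data pathologies.

## Numerical notes and degenerate inputs

* Percentile thresholds are order statistics — no interpolation anywhere.
* `filter_loops` is strict (`q < cutoff`); a loop at exactly the cutoff is
  removed. Loop distance is midpoint-to-midpoint; a distance exactly at
  200 kb counts as long.
* Empty interval sets are legal inputs to every overlap operation; the
  Jaccard index of two empty sets is 0.
* An all-zero contingency table has p = 1; `k = 0` in the projection and
  hypergeometric tests gives p = 1 exactly.
* Bootstrap and generator seeds are explicit arguments with fixed
  defaults; every generator is a deterministic function of
  `(config, seed)`.

## Known limitations

Per-base coverage vectors are materialised per chromosome, which is
comfortable at tens of megabases but not designed for whole mammalian
genomes; a production deployment on full-size data would swap the coverage
backend for run-length encodings while keeping the same interfaces. The
pause-index module assumes one TSS/TES per gene id (isoform selection is
upstream). The MR module implements fixed-effects IVW only; MR-Egger and
weighted-median sensitivity analyses are out of scope.
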