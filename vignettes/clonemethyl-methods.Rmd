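---
title: "Methods: two-group MeDIP-seq and RNA-seq differential analysis"
author: "clonemethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-group MeDIP-seq and RNA-seq differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design this package models

`clonemethyl` re-implements, as tested and reusable code, a common design in
cloned-animal epigenomics: two pooled, unreplicated libraries per assay — an
"abnormal" group (A) and a "normal" group (B) — profiled by MeDIP-seq
(immunoprecipitated methylated DNA, where read density proxies DNA
methylation) and by RNA-seq (tag counts per gene). The analysis chain is:

1. window-normalised methylome profiles and read proportions over gene
   elements,
2. Poisson peak calling per group,
3. chi-square + FDR + fold-change differential methylation over the union
   of peaks, annotated to gene elements (DMRs and DMGs),
4. a two-proportion *u*-test for repetitive-element read fractions,
5. an exact conditional (Audic–Claverie-style) test for differential
   expression between the two RNA libraries (DEGs), with RPKM expression
   tiers,
6. integration: expression-tier-stratified metagene methylation profiles
   and the DMG × DEG overlap, plus the arithmetic of the two wet-lab
   validations (bisulfite-clone chi-square, qPCR $2^{-\Delta\Delta C_T}$).

Because the design has no biological replicates, both differential tests are
sampling-noise tests: they ask whether two count observations are consistent
with one underlying rate, not whether a difference generalises across
animals. That caveat applies to the original design and is inherited here.

# Models and statistics

## Window normalisation

The genome is tiled in fixed windows (default 10 kb) and each window's read
count $RC$ is scaled to $RC \times 10^6 / URC$, where $URC$ is the library's
unique mapped read count. A read is assigned to the window containing its
leftmost aligned base; with 49-bp reads and 10-kb windows the choice of
anchor is immaterial, and a single stated rule keeps the conservation
identity exact: summed normalised depth equals $10^6 \times$ (assigned
reads)$/URC$.

## CpG island detection

Only the thresholds of the island definition are fixed by the field
(length > 200 bp, G+C > 50%, observed/expected CpG > 0.60, with
$\mathrm{obs/exp} = n_{CpG} \cdot L / (n_C \cdot n_G)$). The search strategy
is the package's own choice, in the Takai–Jones style: slide a 200-bp window
at 1-bp resolution, merge qualifying windows that overlap or abut, anchor
the merged region to its first and last CpG dinucleotide, and trim one base
from each side (re-anchoring) until the region itself satisfies all three
criteria, else drop it. Two details are deliberate:

* **CpG anchoring** prevents a short CpG-rich feature (≤ 200 bp) from being
  reported merely because 200-bp windows padding it with neutral flank still
  clear the thresholds — the reported island is supported by CpGs at both
  ends.
* **Symmetric trimming** makes the detector exactly mirror-symmetric under
  reverse complementation (CpG counts are strand-symmetric), which the test
  suite asserts as an invariant.

`N` bases are excluded from all counts and from the effective length.

## Poisson peak calling

A deliberately simple global-background model: windows of 100 bp, background
rate $\lambda = URC \times w / G$ with $G$ the effective genome length, a
window significant when $P(X \ge RC \mid \lambda) < 0.05$, adjacent
significant windows merged (the merged peak keeps the summed count and the
minimum p). The local-$\lambda$ and model-shift machinery of full ChIP-seq
callers is intentionally not reproduced: the global model is deterministic
and oracle-checkable against direct Poisson tail summation, which the
acceptance suite does for all counts up to 200 against a grid of
$\lambda \le 50$. The `effective_length` argument is the hook for excluding
unassembled sequence from the background; the default uses the full
chromosome lengths.

## Differential methylation

Candidate regions are the merged union of both groups' peaks. Per region,
the read counts form a 2×2 table against the remainder of each library and
are tested with Pearson's chi-square without continuity correction — chosen
because it is exactly the squared pooled two-proportion z statistic, which
gives the suite a second independent oracle. Benjamini–Hochberg correction
runs across all regions. A region is called hyper- or hypomethylated in the
abnormal group only if all of: $p < 0.05$, $q < 0.05$, at least one read
from *each* group in the region ("covered by both"), and a strictly greater
than twofold difference of the *per-million normalised* counts. Normalised
(not raw) folds are used because the libraries differ in depth; raw-count
folds would bias calls toward the deeper library. Both the nominal and the
FDR-adjusted gate are applied because the source description lists the two
criteria without separating them; both thresholds are arguments.

A DMG is any gene whose span ± 2 kb overlaps a called region. Element
classes (upstream 2 kb, 5′UTR, CDS, intron, 3′UTR, downstream 2 kb, CpG
island, repeat) are deliberately **not** mutually exclusive — a called
region inside an intronic repeat increments both classes, matching how
element proportions are usually reported.

## Repeat-category u-test

Per repeat category, the fractions $x_A/n_A$ and $x_B/n_B$ of each library's
reads falling in the category are compared with the pooled two-proportion z
statistic; $|u| > 1.96$ marks a difference. The denominators default to the
unique mapped read counts of the libraries. The published u values of the
motivating study are not reproducible from its printed counts under any
obvious denominator, so the implementation fixes this defensible default,
exposes the denominator as an argument, and the tests assert only sign,
significance and the exact antisymmetry under group exchange.

## Digital expression test

For tag counts $x$ (library 1, size $N_1$) and $y$ (library 2, size $N_2$),
conditional on $x$ the second count follows

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

and the two-sided p-value doubles the smaller tail, capped at 1. Tails are
accumulated in log space; the upper tail is summed directly rather than via
$1 - F$, which would lose all precision below $\sim 10^{-16}$. This
conditional statistic is only *approximately* symmetric under exchanging
the libraries — a known property of the statistic; the suite asserts exact
pmf symmetry at equal library sizes, closeness of the two orientations, and
identical significance decisions, not exact equality.

DEGs require $q \le 0.001$ (BH over genes with at least one tag) and
$|\log_2(\mathrm{RPKM}_A/\mathrm{RPKM}_B)| \ge 1$. A gene expressed in only
one library has an infinite log ratio; it is callable when its nonzero
count reaches a minimum (default 5) — a minimum-evidence gate rather than a
pseudocount, because the published ratios are finite only for
doubly-nonzero genes and no pseudocount is stated anywhere.
$\mathrm{RPKM} = \mathrm{count} \times 10^9 / (\mathrm{length}_{bp} \times
\mathrm{library})$. Expression tiers on RPKM are right-closed: silent $=0$,
low $(0,1]$, medium $(1,10]$, high $(10,1000]$; above 1000 is excluded, and
genes silent in both groups or excluded in both are dropped from profile
analyses.

## Metagene profiles

Each 2-kb flank is cut into 20 fixed 100-bp bins; the region body is
rescaled to 40 bins (genes) or 20 bins (CpG islands). Minus-strand regions
are reversed so bin 1 is always biological upstream. A bin's value is the
number of reads overlapping it (≥ 1 bp), summed over regions, scaled by
$10^6/URC$ and divided by the region count. Regions shorter than the body
bin count are skipped with a warning. Tier-stratified profiles assign each
gene the tier of *that group's own* RPKM, so a gene may contribute to
different tiers in the two panels — matching how per-group panels are drawn.

## Validation arithmetic

The bisulfite-clone comparison is a 2×2 Pearson chi-square (df = 1, no
continuity correction) of methylated/unmethylated CpG calls by group, with
a soft warning below 15 calls per group. qPCR uses the single-replicate
Livak form: $\Delta C_t = C_t^{target} - C_t^{ref}$ per condition,
fold $= 2^{-\Delta\Delta C_t}$; replicate $C_q$ values are averaged before
the deltas.

# The synthetic data generator

The generator defines the study conditions under which everything is
tested; its defaults are fixed once:

* two 1-Mb chromosomes; 200 non-overlapping multi-exon genes (2–6 kb, both
  strands, CDS leaving UTR stubs); 30 repeats in each of seven categories
  named after the field's repeat taxonomy; 40 planted CpG islands of
  1.2–2 kb. Island sequence is CpG- and GC-rich against a CpG-depleted
  AT-rich background — sized so the detector, whose boundaries are fuzzy by
  up to ~100 bp (a 200-bp window threshold effect), recovers every planted
  island with Jaccard ≥ 0.8. Real CpG islands average about 1 kb, so this
  is also the realistic regime.
* MeDIP reads: 49 bp (the assay's read length), ~300,000 unique reads per
  group drawn from a piecewise-constant intensity (background 1, multiplied
  by each truth region's enrichment), so per-window counts are Poisson and
  the total is Poisson(depth). Total reads are back-computed from a 50%
  unique-mapping rate to populate the summary table realistically.
* planted methylation truth: 40 hyper (4× in A), 40 hypo (4× in B) and 200
  null regions of 1 kb. Null regions carry the *same* 3× enrichment in both
  groups rather than flat background: they then become peaks in both
  groups, enter the candidate set, and genuinely exercise the caller's
  false-positive gates — flat nulls would never even be tested. At these
  depths every planted region expects well over 100 reads.
* expression truth: lognormal baseline RPKM spanning the low/medium/high
  tiers, 20 up and 20 down genes at 4×, a quarter of each as complete
  on/off switches so the silent tier is populated per group; counts are
  Poisson with mean $\mathrm{RPKM} \times \mathrm{kb} \times
  \mathrm{library}/10^6$ against a notional library of 2 × 10^6 mapped
  tags. Overdispersion is deliberately absent: the expression test itself
  assumes Poisson sampling, so the generator matches the test's model; on
  real replicated data both would understate biological variance.

What passing recovery tests shows, therefore, is that the implementation
correctly identifies its own model's signals at the stated effect sizes and
depths — not that the thresholds are well calibrated for overdispersed,
GC-biased, fragment-size-confounded real libraries.

Everything is reproducible from one integer seed; each generator stage
derives an independent substream, and the test suite asserts byte-identical
fixture files and pipeline outputs across reruns.

# Numerical choices and degenerate inputs

* Report-table rounding is half-away-from-zero at 2 decimals (1 decimal for
  overlap percentages), matching the source tables' arithmetic.
* Regions with zero reads in both groups get $p = 1$ by convention; a
  pooled repeat proportion of 0 or 1 defines $u = 0$; a zero margin in the
  bisulfite table returns $p = 1$ with a warning; empty gene sets make
  overlap percentages `NA` rather than dividing by zero.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the hand
  step-up computation is kept in the tests as the oracle.
* Chi-square statistics are computed from the closed 2×2 form; `pchisq`
  and `ppois` provide the distribution tails.
* Coordinates are 1-based closed `GRanges` throughout; BED is converted
  from 0-based half-open at the file boundary and GTF read as 1-based
  inclusive. Genes collapse to the union of their transcripts' exons;
  exonic bases inside the CDS span count as coding, bases strand-5′/3′ of
  it as UTR, so per gene UTR ∪ CDS ∪ intron tiles the span exactly (a
  tested invariant).

# Problem sizes

The shipped analyses and tests run the default conditions above: a 2-Mb
genome, ~600,000 MeDIP reads per run, 280 truth regions and 200 genes.
These sizes were chosen so the planted effects sit far from the decision
boundaries (hundreds of reads per region, tens of tags per gene) while the
full workflow — simulation, both methylome passes, both tests and the
integration — completes in well under a minute; scaling the configuration
up is a matter of `simulation_config()` arguments.

# Known limitations

* No replicate-aware dispersion modelling in either assay (the design is
  unreplicated pools; see above).
* The peak model is global-λ; no CpG-density (coupling-factor) correction,
  fragment-size model or strand-shift estimation.
* The *u*-test denominator is a documented default, not a reproduction of
  the source's (unstated) choice.
* Transcript isoforms are collapsed per gene; the expression unit is the
  gene.
* The DMG definition (span ± 2 kb overlapping a called region) is one of
  several defensible readings and the reported DMG counts depend on it.
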