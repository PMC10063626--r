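---
title: "Methods: binomial loop calling and downstream HiChIP analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binomial loop calling and downstream HiChIP analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopforge)
```

## The problem

HiChIP combines Hi-C proximity ligation with chromatin immunoprecipitation,
so the interactions it recovers are anchored at ChIP peaks of the targeted
mark (H3K27ac for active enhancers/promoters, CTCF for structural loops).
Anchor-level callers emit, per library, a BEDPE table of intra-chromosomal
anchor pairs with the number of mated paired-end (PE) read pairs supporting
each. loopforge starts there: it decides which of those candidate loops are
statistically reliable, quantifies and annotates them, compares conditions,
and integrates loop changes with TF binding and gene expression. Only
intra-chromosomal loops are considered throughout; anchors are typically
~2.5 kb wide.

## The binomial significance model

`call_loops()` models the null in which every mated PE read falls on any
*possible* loop with equal probability. The possible-loop universe is
estimated per chromosome. Observed anchors are the distinct anchor
intervals that appear in at least one loop. Regions carrying a ChIP peak
but no reads are potential anchors; because one anchor can span several
peaks, the total is estimated by proportionality — the fraction of the
anchor universe that is observed is taken to equal the fraction of ChIP
peaks falling inside observed anchors:

$$N_{possible}^{(i)} = \left[\frac{N_{obs}^{(i)} \cdot N_{peaks}^{(i)}}
  {N_{peaks\,in\,obs}^{(i)}}\right],
\qquad
N_{possible\,loops} = \sum_i \binom{N_{possible}^{(i)}}{2},$$

with $i$ ranging over chromosomes and $[\cdot]$ nearest-integer rounding
(half-up; floor is available via `rounding = "floor"` and differs
negligibly). Each read then hits one specific loop with probability
$p = 1/N_{possible\,loops}$, and a loop carrying $m$ of the $n$ total reads
is scored by the binomial upper tail

$$P(X \ge m) = \sum_{k=m}^{n} \binom{n}{k} p^k (1-p)^{n-k},$$

computed through the survival function for numerical stability. The PMF
alone cannot rank loops, so the upper tail — the standard enrichment
direction — is used. A chromosome whose observed anchors overlap no ChIP
peak violates the model's premise and raises an error rather than a
guess.

Two scope choices were genuinely open and are fixed as follows: $p$ is
global (one universe summed over chromosomes, not per-chromosome) and $n$
is the genome-wide total corrected strength, so the model is fitted once
per library. P-values are corrected by the Bonferroni–Holm step-down
procedure — a family-wise error-rate control — and loops with adjusted
p below `alpha` (default 0.05) are reported significant. The output column
is deliberately named `p_adj` from Holm, not an FDR;
a Benjamini–Hochberg alternative is available (`adjust = "BH"`) for
sensitivity analyses. Ties in Holm are handled by the max-cummax
formulation, so tied raw p-values always receive equal adjusted values.

### Anchor-length correction

Wider anchor pairs collect more reads for the same contact. "Strength
corrected by anchor length" is implemented as rescaling to a reference
span: $m = [c \cdot s_{ref} / (w_a + w_b)]$ where $s_{ref}$ is the
library-wide median of summed anchor widths. This keeps $m$ integer-valued
(required by the binomial), leaves equal-width libraries unchanged, and
never maps a supported loop to zero. Division, regression, or other
readings of the correction are possible; the strategy is switchable
(`correction = "none"`) and recorded in the fit's audit record. Loops
closer than `min_distance` (default 10 kb, the cis-far di-tag floor) are
excluded before fitting.

## Normalization and annotation

Loop strength comparisons across libraries divide raw counts by the
library's total cis-far unique valid pairs (a whole-library sequencing-depth
measure from upstream QC, supplied as metadata) and rescale to reads per
100 M pairs. Two loops in different libraries are "common" when both left
anchors and both right anchors overlap by at least 1 bp; a one-anchor match
is specific. No reciprocal-overlap fraction is imposed by default since
none is standard for anchor-level loops. Anchor H3K27ac status is the
unordered pair of per-anchor peak overlaps (`+/+`, `-/+`, `-/-`); "strong"
loops are those with more than 10 mated PE reads. Loop distance is always
midpoint-to-midpoint of the anchors, which is robust to unequal anchor
widths. Genes are tied to anchors when their TSS lies within a 3 kb window
around the anchor; the same window serves promoter-anchored strength
aggregation. Gene density inside a loop counts TSSs strictly between the
anchor midpoints per Mb (gene bodies are not used; TSS counting is the
flagged choice).

## Differential looping

No replicate structure is assumed: each loop is tested with a two-sided
Fisher exact test of its count against the remainder of the library's
cis-far total in both conditions — an assumption-light test of equal
per-read loop rates between libraries of different depths. This procedure
is an interpretation (the choice of test for unreplicated HiChIP libraries
is not standardized), and is documented as such. Loops with a summed count
below `min_total` (default 5) are reported untested. Benjamini–Hochberg
correction is applied across tested loops, and a directional call
additionally requires the depth-normalized fold change to exceed 1.5
(pseudocount 0.5, rescaled like the counts, keeps fold changes finite).
Swapping the two libraries exactly negates the fold changes and preserves
the p-values.

## Observed-vs-expected anchor enrichment

To ask whether dysregulated-loop anchors preferentially carry a TF's
binding, the observed overlap fraction of the target anchor set is
compared against `B = 500` random draws of the same number of anchors
from the full anchor universe of the same mark, sampled without
replacement within each draw. O/E is the observed fraction over the null
mean. Significance is reported both as a two-sided one-sample t-test of
the null fractions against the observed value and as an add-one-smoothed
empirical upper-tail p-value; the t-test against a constant is
anti-conservative when the null is skewed at small B, so the empirical
p-value is the safer headline number. Draws are seeded and bit-for-bit
reproducible; the caller's RNG state is left untouched. No GC- or
length-matched sampling is attempted.

## Crossover (insulation) analysis

A gained CTCF loop can insulate an enhancer–promoter contact when its
anchors interleave the contact's anchors. `find_crossings()` encodes this
as: exactly one of the CTCF loop's anchor midpoints lies strictly inside
the open interval between the H3K27ac loop's anchor midpoints. Nested and
disjoint configurations are excluded by default (a nested-inclusive mode
exists, `mode = "nested_inclusive"`). Crossed H3K27ac loops are mapped to
promoters by the 3 kb TSS window, and the resulting gene set is tested for
association with down- versus upregulated genes in a Yates-corrected 2x2
chi-square; the continuity correction is the default because it is the
common default in standard statistical environments for 2x2 tables.
Differential expression itself is consumed as input gene lists — loopforge
does not refit expression models. Gene-set z-scores standardize each gene
across samples (sample sd, n−1) and average over set genes per sample;
constant genes are dropped, and scores average to ~0 across samples by
construction.

## The synthetic generator

`simulate_hichip()` exists so every stage can be validated against a known
truth without sequencing data. Its defaults are the study conditions used
by the test suite and the acceptance script:

* 3 chromosomes of 30 Mb with 80 anchors per chromosome and mark; anchor
  width constant at 2.5 kb (the field's median anchor width; constant
  widths make the length correction the identity, so the null calibration
  is exact).
* Background counts are one multinomial draw per library over *all*
  possible intra-chromosomal anchor pairs at a uniform expected 2 reads
  per pair — exactly the caller's null, so type-I error is interpretable.
  Read totals are conserved exactly by construction. A deliberately
  misspecified `distance_decay` mode (per-pair rate ∝ 1/distance) is
  available to probe robustness against the contact-distance decay of
  real data.
* 20 planted significant loops per mark at 10x the background rate
  (expected count ~20).
* 10 planted differential loops per mark and 12 "disrupted" genes. These
  sit on a baseline of 20x background (expected count ~40) so that a 4x
  change leaves the weakened condition at an expected count of ~10 —
  chosen a priori so the Fisher test retains power in the down direction;
  a 4x drop from a baseline of 20 would be near the detection floor.
  Disrupted genes get a weakened promoter H3K27ac loop, an interleaving
  CTCF loop gained in condition B, and a 4x expression loss (log-normal
  noise, sd 0.25 log2 units, 3 replicates per condition).
* TF peaks cover exactly 10% of the CTCF anchor universe, arranged so
  40% of the dysregulated-loop anchors are covered — a planted O/E of ~4.

A single master seed drives everything through deterministically derived
sub-seeds; identical seeds give byte-identical bundles. What the generator
does *not* emulate: restriction-fragment structure, anchor-width
variability, replicate correlation, distance decay in the default mode,
and peak-signal realism. Passing tests therefore demonstrate correctness
of the statistics under the model's own assumptions and robustness basics,
not performance on real libraries.

## Problem sizes and numerical choices

The heavier validation suites run on reduced instances (2 chromosomes, 40
anchors per chromosome) chosen as the package's own balance between
statistical resolution and turnaround: 200 null libraries for family-wise
error, 50 seeds for recovery/power properties, 100 seeds for enrichment
calibration. Empirically the caller's family-wise error on null libraries
is ~1% at alpha 0.05 (the binomial tail is conservative on discrete
counts), planted-loop sensitivity is ~0.97, and differential sensitivity
at the planted effect sizes is ~0.9.

Rounding of the anchor-universe estimate and of corrected strengths is
half-up (`round_half_up()`), not banker's rounding. Significance uses a
strict `p_adj < alpha` comparison; the degenerate `alpha = 1` is treated
as "everything passes" since Holm caps adjusted values at 1. Upper-tail
binomial probabilities come from `pbinom(..., lower.tail = FALSE)`; the
test suite checks them against explicit log-space PMF summation to 1e-12.
Empirical enrichment p-values are add-one smoothed and can never be 0.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_hichip(sim_config(seed = 7))
fit <- call_loops(sim$libraries$k27_a, sim$peaks$k27)
summary(fit)
run <- run_pipeline(sim, seed = 7)
run
```

## Known limitations

* The differential test treats each library as one big binomial draw; with
  replicates, a dispersion-aware count model would be preferable. The
  headline changed-loop counts of any particular study depend strongly on
  this choice and on sequencing depth, and are not expected to transfer.
* The anchor-universe estimate inherits the proportionality assumption;
  anchors systematically devoid of peaks violate it and are reported as
  errors, not imputed.
* Enrichment sampling is not covariate-matched (GC, length, distance).
* The crossover geometry is midpoint-based; anchors wider than the spacing
  between them could blur interleaved versus nested calls.
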