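---
title: "Quantifying meiotic bouquet chromosome architecture from Hi-C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meiotic bouquet chromosome architecture from Hi-C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

During fission-yeast meiotic prophase, telomeres cluster at the spindle
pole body and chromosome arms are bundled into the *bouquet*
configuration, while Rec8-cohesin organizes chromatin into an axis-loop
structure. In Hi-C contact maps these two phenomena appear as,
respectively, anti-diagonal "X-shaped" contact bands running from each
telomere corner, and grid-like punctate dots anchored at cohesin sites
together with a "shoulder" in the contact-probability curve P(s).
`meiohic` implements the analysis stack needed to quantify both, plus a
ground-truthed simulator so that every statistic can be validated by
parameter recovery rather than by eye.

The pipeline mirrors the standard in situ Hi-C workflow for a small
fungal genome: aligned read-pair filtering against an MboI fragment map,
binning at 20/5/2 kb, matrix balancing (iterative correction for display
and metrics, Knight-Ruiz for loop calling), and three families of
statistics:

* the **alignment index**, the telomere-proximal extent (in Mb) over
  which expected-normalized anti-diagonal contacts exceed a threshold;
* **P(s)** with Loess-smoothed log-log derivatives and a
  second-derivative transition ("shoulder") locator;
* a donut-filter **loop caller** with lambda-chunked FDR control and a
  loops-per-length summary.

# Filtering model

A read pair survives filtering unless it fails one of five rules,
applied in a fixed order so the bookkeeping is deterministic and the
report categories partition the input exactly:

1. **PCR duplicate** — identical `(chrom, pos, strand)` of both mates
   after canonical mate ordering; the first occurrence is kept. Strand
   is part of the key: two fragments ligated at the same positions but
   in different orientations are distinct ligation events.
2. **Repetitive / unassigned** — a mate without a fragment assignment
   (unknown chromosome, out-of-range position) or inside a
   user-supplied exclusion blacklist. No blacklist is built in; the
   caller decides what counts as repetitive for their assembly.
3. **Low mapping quality** — `min(mapq1, mapq2) < 30` by default.
4. **Self-ligation** — both mates on the same restriction fragment,
   any orientation.
5. **Undigested product** — mates on adjacent fragments in inward
   orientation (`+` upstream, `-` downstream), the signature of a
   read-through over an uncut site.

MboI cut sites are placed at the first base of each GATC match; any
fixed convention works as long as it is consistent, and this one makes
fragment maps reproducible from sequence alone. A site at position 0
produces a zero-length leading fragment (fragment count is always cuts
+ 1); such a fragment can never receive a read.

# Balancing

`ice_balance()` performs iterative correction: each round divides every
entry by the product of its row and column bias (the marginal rescaled
to mean 1 over unmasked bins). The default is 30 rounds, which leaves a
marginal coefficient of variation around 1e-5 on well-conditioned
matrices; `tol` iterates to convergence instead. `kr_balance()`
implements the Knight-Ruiz inner-outer Newton iteration with conjugate-
gradient inner solves; both solve the same doubly-stochastic fixed
point, and the test suite checks both against an independent
brute-force alternating-normalization loop. Bins with zero raw marginal
are masked before balancing. Disconnected contact support is balanced
per connected component with a warning, since a global scaling does not
exist across components. The bias vector is stored divisively
(`normalized = raw / (bias_i * bias_j)`) for both methods. KR input is
pre-scaled by its mean row sum for numerical headroom; the weights are
rescaled back, so the output is unchanged.

Display transforms follow the heatmap conventions of the field:
`percent_rank_scale()` maps nonzero scores to their percentile rank and
saturates everything at or above the 95th percentile at full intensity;
`subtraction_map()` reports `T`, the 95th percentile of |A - B| over
the union of supports (exact cancellations included), and clips the
display at [-T, +T]. All percentiles use linear interpolation between
order statistics (type-7), stated so that `T` is bit-reproducible.

# The alignment index

For a chromosome of `n` bins the anti-diagonal profile evaluates, at
each distance `d` (bins) from the chromosome ends, the mean of
`c(i, j) / E(|i - j|)` over a band of half-width 1 bin around the pixel
pairing the bin `d` from the left telomere with the bin `d` from the
right telomere. The band is the union of row- and column-offset pixels,
which makes the profile exactly invariant under relabeling the two
chromosome ends. `E(s)` is the same-chromosome mean contact at
separation `s`, with two stabilizations:

* a band of half-width 2 bins around the anti-diagonal is **excluded**
  from `E`. At separations close to the chromosome length nearly every
  pixel lies on the anti-diagonal, so an unexcluded mean would be
  dominated by the very bouquet signal being measured and the profile
  would collapse toward 1 near the telomere corner;
* `log E` is lowess-smoothed against `log s` (span 0.3), because the
  largest separations are estimated from a handful of pixels.

Expected-normalization makes the profile invariant under global scaling
of the matrix, so one threshold works at all distances. The index is
the first downward crossing of the 3-bin moving-average profile below
the threshold (default 2.0 x expected, exposed as a parameter),
reported in Mb; a profile below threshold at the first evaluable
distance gives 0, and one that never drops gives the full profile
extent. Two domain rules matter in practice:

* the profile stops at the shorter arm when a centromere is annotated
  (beyond it the anti-diagonal leaves the matrix);
* the crossing scan starts at the first distance whose centered
  smoothing window is complete. At `d = 1` the expected model rests on
  at most two background pixels and a single Poisson fluctuation could
  otherwise zero the index; at typical depths (about 1e6 cis pairs per
  chromosome) the statistic is stable from `d = 2` on. At much lower
  depth the threshold crossing near the corner remains the noisiest
  part of the statistic — a known limitation.

`cluster_enrichment()` quantifies telomere and centromere clustering as
the mean normalized trans contact between two region sets divided by
the mean over all unmasked trans pixels; it equals 1 on a homogeneous
matrix, and because the background mean includes the enriched blocks it
slightly understates a planted fold change on small genomes.

# P(s), smoothing and the shoulder

`compute_ps()` pools all intra-chromosomal unmasked bin pairs into
log-spaced distance bins (8 per decade) from a minimum separation of 2
bins, where self-ligation remnants no longer dominate. Per bin,
`P = sum(scores) / number of evaluable pairs`; the curve is then
area-normalized (`sum(P * ds) = 1`) so curves from different
sequencing depths overlay. Smoothing is local linear regression of
log10 P on log10 s with tricube weights (span 0.3 by default); a power
law is reproduced exactly, so the slope estimate is unbiased where the
decay is scale-free. Derivatives are centered finite differences,
one-sided at the boundaries.

The shoulder is located as the **minimum of the second derivative** —
the point of maximal downward curvature, where contact enrichment below
the chromatin loop length rolls over into the background decay. The
alternative reading (a zero crossing of the second derivative) is not
used; the choice is recorded in the output metadata (`rule` field). A
transition is only reported when |curvature| reaches 0.05 per decade^2,
which suppresses spurious calls on nearly pure power laws. On sampled
finite chromosomes the arm-length rolloff itself carries curvature, so
comparisons between conditions should use a search window around the
loop scale (the package defaults to the full range and exposes
`window`).

# Loop calling

`call_loops()` re-implements the donut-filter dot test: for every
candidate pixel (nonzero raw count, separation between 4 bins and 1 Mb)
the observed raw count is tested against a Poisson rate derived from
four local neighborhoods of the KR-normalized matrix — donut,
lower-left quadrant, horizontal and vertical stripes (peak half-width
p = 3, outer half-width w = 7 at 2 kb). Each neighborhood mean is
rescaled by the distance-decay expected at the pixel's separation and
converted back to raw-count units through the bias vector.
Neighborhoods are clipped at matrix borders and at the diagonal by
construction (cells at or below the diagonal contribute to neither
numerator nor denominator); a pixel whose neighborhood is entirely
unavailable under some model is skipped. Neighborhood sums use
summed-area tables, so the caller is O(1) per pixel after an O(n^2)
precomputation.

P-values are Benjamini-Hochberg corrected *within lambda chunks* —
pixels grouped by expected value at powers of 2^(1/3) — at FDR 0.01,
and a call additionally requires fold enrichments of 1.75x over donut
and lower-left and 1.5x over the stripes. Significant pixels are
clustered by 8-connectivity; each cluster is summarized by its
strongest pixel (largest observed/donut-expected; ties broken by
smaller row then column, for determinism), and a call whose centroid
lies within 10 kb (Euclidean, in bp) of a stronger call is absorbed.
Merging is idempotent and the BEDPE output is byte-identical across
reruns. `loops_per_length()` histograms call lengths per Mb of genome
for between-strain comparisons.

# The simulator and what passing tests mean

`sim_config()` defines a rate model, not a polymer model: contacts are
Poisson draws from a constructed intensity surface, which gives exact
planted truth for recovery tests at the cost of biophysical realism.
The surface composes:

* cis background `s^-alpha` (default alpha = 1, the generic
  scale-free decay regime);
* an anti-diagonal band (half-width 1 bin) multiplied by
  `1 + align_enrich` out to the planted extent from each telomere
  corner (defaults: enrichment 3, extent 0.9 Mb — just under the
  shortest arm of the toy genome, since the extent may not exceed an
  arm);
* dots of `1 + loop_enrich * K` (default 4, so 5x at dot centers) at
  anchor-pair grid points, `K` a truncated Gaussian of half-width 1
  bin; anchors default to a 20 kb grid (the wild-type loop scale) and
  interact up to `loop_reach` neighbors apart — 1 for wild-type-like
  short loops, 2 for fused wpl1-delta-like loops, 0 for
  rec8-delta-like loss;
* flat trans intensity (15% of total mass) with additive 4x
  centromere-centromere and telomere-telomere blocks
  (`1 + beta`, beta = 3) emulating Rabl and bouquet clustering.

The default toy genome is three chromosomes of 4/3/2 Mb with central
40 kb centromeres and 60 kb telomere margins — about a quarter of the
fission-yeast scale, so the full pipeline runs in seconds;
`toy_genome(scale = 4)` reproduces real matrix dimensions for
performance checks. `sample_pairs()` additionally emits read-level
records with planted fractions of duplicates, low-MapQ, same-fragment
and adjacent-inward contaminants for end-to-end filter audits; planted
fractions are recovered on top of a small chance background (~0.2-0.5%
of diagonal-bin pairs fall on one fragment at 20 kb bins).

What the simulator does **not** emulate: loop-extrusion dynamics,
horsetail nuclear movement, homolog-distinguishing variants (the
diploid homologs are sequence-identical, so cis/trans arm alignment is
all Hi-C can see), copy-number or mappability structure, and
distance-dependent trans decay. Tests passing on simulated maps
therefore demonstrate that the statistics recover planted geometry at
realistic depth and noise — not that the biological estimates on real
data are unbiased.

# Problem sizes and reproducibility

The shipped validation suite uses: 10x10 matrices (20 random seeds) for
the balancing oracle; a single 4.2 Mb chromosome at 20 kb, depth 1e6,
planted extents 0.25-2 Mb over 10 seeds for alignment recovery; 5 kb
maps at depth 2e6 for the decay exponent; a 2 Mb chromosome at 2 kb,
depth 2.5e6, for loop-null calibration and the strain-direction
comparisons (10 seeds); and a 4.2 Mb chromosome with 51 anchors at
depth 5e6 for 50-dot recovery (5 seeds). These sizes were chosen so the
whole suite completes in a few minutes while keeping per-pixel counts
in the regime where the statistics are specified to be stable. Every
sampled object carries its seed; identical configurations are
byte-identical end to end, including the pipeline manifest.

# Known limitations

* The alignment-index threshold is a free parameter; published indices
  from other processing stacks depend on their exact normalization and
  threshold, so cross-stack comparisons should calibrate the threshold
  on shared data first.
* The expected models (profile and loop caller) are estimated from the
  same matrix being tested; on very small chromosomes the planted
  signal leaks into its own expected (mitigated, not eliminated, by
  the anti-diagonal exclusion band).
* The loop caller tests only pixels with nonzero raw counts, which is
  exact for calling (a zero count is never significant) but means
  q-values are computed over a slightly smaller test family than an
  exhaustive scan.
* `cluster_enrichment()` uses the global trans mean as background;
  distance-matched cis backgrounds are out of scope.
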