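---
title: "Methods: TFBS-clustered region discovery and its downstream analyses"
author: "tfcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TFBS-clustered region discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfcr)
```

## The problem

Transcription-factor binding sites (TFBSs) are not scattered uniformly:
the bulk of sites concentrates in a small fraction of the genome, in
clusters roughly 600 bp wide whose internal spacing is well described by
a geometric distribution with mean near 46 bp. `tfcr` identifies these
clusters per cell type, scores how many factors effectively co-occupy
each one, and supports the comparative analyses that follow: which
clusters recur across cell types, how their number saturates as cell
types accumulate, how chromatin is organised around them, how their
presence/absence encodes developmental lineage, and how constrained
they are evolutionarily.

## Region calling

**Model.** Each site contributes an *unnormalised* Gaussian kernel
`k(d) = exp(-d^2 / (2 b^2))` centred on its anchor; the density is the
kernel sum. The kernel is deliberately not a probability density:
`k(0) = 1` makes the density an *effective local site count*, which is
what gives the contribution threshold θ = 0.1 and the count-like
category bounds (6 … 30) their meaning.

**Anchors.** A site's anchor is its interval midpoint rounded down. The
source method centres the kernel "on each TFBS" without fixing the
anchor; the midpoint is the symmetric choice and the one under which a
width-w site contributes the same mass on both sides.

**Peaks, complexity, windows.** Every strict local maximum of the
density (plateaus: midpoint, rounded down) is a candidate region. The
peak *location* uses the full untruncated density; the *complexity* C
sums only contributions ≥ θ, following the stated "contributed at least
0.1" rule. The window half-width is the maximum contributing distance
plus half the bandwidth (150 bp at defaults), centred on the peak.
Peaks whose every site falls below θ (possible where far tails overlap)
are dropped. Two equal sites merge into one peak exactly when separated
by ≤ 2b — the classical two-Gaussian mode condition — which the test
suite checks both ways around the boundary.

**Numerical choices.** The density is evaluated per site over a window
beyond which the kernel underflows to exactly zero in double precision
(≈ 11.6 kb at b = 300), accumulating site-by-site in sorted order. This
makes the fast path *bit-identical* to a naive per-base sum — the
acceptance suite asserts exact equality of peaks and complexities
against an independently written brute-force caller on 200 random
instances. Grid step defaults to 1 bp; coarser grids are permitted for
exploration but all tests run at 1 bp.

**Categories.** TC0–TC8 hold complexities below
6, 8, 10, 12, 14, 16, 19, 23, 30; TC9 holds the rest. The boundary
value 30 is unassigned in the source text ("less than 30" / "greater
than 30"); it is assigned *upward* (TC9) so that every bound behaves
half-open identically. HOT regions have strictly more than 40 distinct
contributing factors; COLD regions are TC0.

**Gap mixture.** Adjacent-site gaps are modelled as a two-component
geometric mixture on support {1, 2, …} fitted by EM (k-means on log
gaps for initialisation, 10 restarts, log-likelihood tolerance 1e-8).
The within-component 99.5% quantile — the model's cluster-width
estimate — has closed form `ceil(log(0.005)/log(1 - 1/mean))`, which is
242 bp at mean 46 (the often-quoted "≈ 600 bp" cluster width comes from
the *fitted* mixtures of real data, not from a pure geometric(46), and
is reported, never asserted).

## Master list and saturation

Pooled per-cell regions are consolidated one winner at a time: within a
connected component of overlapping windows the highest-C region enters
the master list, every region overlapping it is discarded, and the
selection repeats on the remainder. Ties break by leftmost start, then
cell-type name, which makes the result invariant to input order (tested
by permutation). Because removals never join components, components can
be processed independently — the implementation does, the semantics are
the literal iterative text.

Saturation draws cell-type subsets of each size (all of them when fewer
than `n_samples` exist, otherwise random draws), merges the members'
windows, and chunks merged runs longer than 5000 bp into consecutive
≤ 5000 bp elements — the published figure caps element length at
5000 bp without stating the mechanism; chunking is the parameterised
choice here. The curve is fitted with
`y(x) = A (1 - exp(-(x/lambda)^k))` by multi-start least squares on log
parameters. A saturated (constant) curve leaves A unidentified along a
flat SSE ridge; among numerically tied optima the smallest asymptote is
reported, so a constant curve yields A ≈ its level. Recovery note: on a
λ = 10 curve observed to x = 40 (≈ 98% of saturation, comparable to
having 100+ cell types), A is recovered within 5% at 1% noise across
seeds; truncating observation at x = 20 leaves A statistically
unidentified at that tolerance — a property of the design, not the
optimiser.

Genomic classes follow the strict priority promoter > exon > UTR >
intron > intergenic: promoter means the region *peak* lies within 1 kb
of a TSS; exon requires a single CDS segment overlap of ≥ 75 bp; UTR
and intron require ≥ 1 bp. Nearest genes minimise |TSS − region
centre|, ties lexicographic.

## Signal profiles and enrichment

Aggregate profiles average track values over ±5 kb around region
centres in 50 equal bins, scaled to reads per million per bp. The
profile is linear in the track (tested), and regions too close to a
chromosome edge are skipped with a warning.

The published enrichment analysis uses the ENCODE genome-structure
correction. `tfcr` implements the same *intent* — preserve the internal
length and spacing structure of the peak annotation under the null —
with a simpler, exactly length-preserving device: within each domain
segment (default: whole chromosomes) the entire peak set is circularly
rotated by a uniform random offset, wrapping split peaks around the
boundary. Significance is "observed overlap fraction outside the
central 95% of the rotation null". This is a reimplementation, not the
ENCODE code; its type-I error is calibrated in the acceptance suite
(200 null simulations, rejection rate within a 3-s.e. binomial band of
5%; the quantile CI makes it mildly conservative).

## Nucleosome structure

Occupancy profiles anchor on region centres at 1-bp resolution.
Positioning strength is the raw DFT magnitude of the mean-subtracted
profile at the bin nearest 1/repeat (default repeat 200 bp; an `"auto"`
mode takes the band-limited argmax over 150–250 bp periods). No taper
or normalisation is applied — the source does not state any — so
magnitudes are only compared between profiles of equal length.
Depletion D is the mean occupancy over two background windows
(extending 100 bp inward from ±2 kb) minus the mean over the central
±50 bp; positive D means a depleted centre.

The synthetic occupancy generator plants a baseline of 1.0, an
edge-phased cosine whose amplitude decays exponentially away from the
region (e-folding 500 bp — positioned arrays in real data lose phase
after a few repeats), a Gaussian central dip (sd 300 bp: effectively
flat across the ±50 bp centre window, negligible at 2 kb), and white
noise. The decay is load-bearing: an undamped cosine reaches the 2-kb
background windows, whose half-period mean would bias D by up to ~0.16.
With it, the acceptance suite recovers planted periods
{180, 200, 220} bp within one frequency bin and dip depth within 5%
over 20 seeds, and power at the repeat is monotone in planted
amplitude.

## Lineage analysis

Cells become rows of a binary matrix over the merged union of all
windows ("reference elements"); an entry is 1 only when a region is
100% contained in the element. Φ is the Euclidean distance between
rows (√Hamming for binary data). Clustering is single linkage — the
natural reading of "nearest-neighbour algorithm" — with deterministic
tie-breaking by smallest minimum-leaf index pair, cross-checked against
`stats::hclust` heights.

**Precursor placement.** Progenitor cell types are assigned to internal
nodes by the Hungarian algorithm on the cost matrix "Euclidean distance
from the precursor's presence vector to the centroid of the leaf
vectors under the node". The centroid cost is an explicit stand-in (the
cited placement method is not specified) and is isolated so alternative
costs can be swapped in. The solver is a shortest-augmenting-path
implementation verified against exhaustive permutation search on 500
random rectangular matrices.

**Dendrogram comparison.** Baker's Γ is the Spearman correlation of the
stages at which leaf pairs first co-cluster. "Stage" is the *dense rank
of the cophenetic merge height*, not the raw merge index: at tied
heights the merge order is arbitrary, and only the height rank makes
Γ(T, T-with-permuted-input) exactly 1 while staying invariant to
monotone height transforms. B_k cuts both trees into k clusters
(applying the first n−k merges, which is deterministic under ties) and
uses `Tk/sqrt(Pk Qk)` with the permutation-null moments; the closed-form
var(B_k) was derived from the permutation distribution and is validated
against a 10^5-permutation Monte-Carlo oracle — a transcription error
in the variance would not survive that test, and one did not.

**Recovery regime.** The lineage generator gains fresh elements on each
branch; leaves inherit their root path. With *equal* gains per branch
the induced Φ is a path-length metric but not ultrametric, and single
linkage can provably mis-cluster unbalanced topologies (a shallow
outside leaf sits closer to a deep clade member than the clade's own
internal minimum — chaining). The generator therefore has a `clock`
mode: branch gains proportional to the drop in node age, so every
root-to-tip path accumulates equally and Φ is ultrametric — the regime
in which single linkage is an exact reconstructor. The 20-seed recovery
criterion runs in clock mode at ≥ 50 gains per branch; equal-gain
recovery on balanced trees is additionally unit-tested. A green
recovery test therefore establishes correctness of the pipeline under a
clock-like world, not consistency of single linkage in general — the
latter is false.

Bootstrap support resamples matrix columns with replacement and counts
how often each internal bipartition (root-agnostic leaf split) recurs.
The sensitivity ensemble enumerates all 2^m − 2 category subsets that
keep ≥ 1 and drop ≥ 1 of the m complexity categories (1022 for m = 10)
in ascending binary-mask order. Lineage-restricted element groups
require presence fraction ≥ α inside a branch and ≤ β outside,
assigning each element to the deepest qualifying branch; the published
analysis names eight groups but defines seven branch points, so group
construction is parameterised rather than hard-coded.

## Conservation

Per region, the score is the best 100-bp sliding-window mean (whole
region when narrower). Group summaries bootstrap 1000 draws × 1000
replicates — reading the ambiguous "1,000 values were sampled with
1,000 replacements" as replicates of draws — reporting the grand mean
and the 2.5/97.5% quantiles of replicate means, resampling at the
*region* level. Nucleotide diversity uses the unbiased per-site
heterozygosity `2 p (1-p) n_h/(n_h - 1)` normalised by unmasked bases;
masks (repeats, exons, CpGs) remove both sites and length, and π is
additive under region splitting (tested).

## What the synthetic world does and does not establish

The generators are pure functions of (seed, config); one global seed
fans out to per-generator substreams through a fixed counter scheme, so
adding a generator never perturbs existing outputs. They reproduce the
*stated* structure of real landscapes — geometric(46) within-cluster
gaps, ~600 bp clusters, planted periodicity and central depletion,
gains along a known tree — on a single 10-Mb chromosome. They do not
model sequence content, read-level noise, mappability, overlapping
cluster interference, region loss along lineages, or cross-factor
correlation. Green tests establish that the estimators recover planted
truth in their stated regimes at desk scale; they do not reproduce
ENCODE-scale numbers (1.58 M regions, 27.7% genome coverage, printed
power magnitudes), which depend on data this package does not ship.

## Known limitations

- The rotation null is a stand-in for the published GSC block
  bootstrap; segmentations finer than whole chromosomes are supported
  but not auto-derived.
- FFT power magnitudes depend on unstated scaling in the source;
  relations between profiles are reproducible, absolute values are not.
- The Hungarian precursor cost and the eighth lineage group are
  explicit design choices where the source under-specifies.
- Saturation chunking of > 5000 bp elements is one consistent reading
  of a figure legend.
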