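---
title: "Tile-path design and sliding-window ChIP-chip peak calling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-path design and sliding-window ChIP-chip peak calling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilepath)
```

## The problem

Histone H3 lysine-4 trimethylation (H3K4me3) concentrates at the 5'
ends of transcriptionally active genes, which makes it an experimental
handle on promoters: map the mark genome-wide and you have found the
active transcription start sites (TSSs), including ones that gene
annotation misses. On draft genome assemblies — amphibian genomes such
as *Xenopus tropicalis* are the motivating case — this matters twice
over, because annotation is incomplete and because assemblies split
genes across scaffolds, leaving "orphan" promoters with no gene model
nearby on their own scaffold.

`tilepath` implements the complete dry-lab side of a tile-path
ChIP-chip workflow on such an assembly:

1. design isothermal tiling probes over the repeat-masked genome;
2. call enriched regions from per-probe log2(ChIP/input) ratios with a
   multi-window sliding-window scan whose thresholds are calibrated on
   randomized probes to a target theoretical false discovery rate;
3. assemble a promoter-focused second-generation array design from the
   enriched regions, annotated gene 5' ends and EST-derived TSS
   clusters, under a fixed probe budget;
4. annotate the peaks: gene association, replicate correlation, TSS
   meta-profiles, overlap with independent peak sets, and EST-based
   linkage of orphan promoter scaffolds to gene-body scaffolds.

A simulation module generates genomes, gene models, probe signals and
split-scaffold ESTs with known ground truth, so every step can be
exercised and scored without any external data.

## Probe tiling and the melting-temperature model

Tiling arrays hybridize best when all probes share approximately the
same melting temperature (Tm). `tile_scaffold()` therefore varies probe
*length* (50–75 bp, `min_len`/`max_len`) at fixed anchors to approach a
common target Tm (76 °C, `target_tm`). Anchors sit on a fixed grid
every `spacing` = 100 bp from the scaffold start; on unmasked sequence
the start-to-start spacing is therefore exactly 100 bp, and masked
anchors are simply skipped rather than re-spaced. A probe overlapping
the repeat mask at any base is rejected outright — repeats are excluded,
not trimmed around.

Tm is computed by unified nearest-neighbor thermodynamics: enthalpy and
entropy sums over the ten Watson–Crick dimer stacks plus terminal
initiation terms, an entropic monovalent-salt correction
$0.368\,(N{-}1)\ln[\mathrm{Na^+}]$, and the $R\ln(C_T/4)$ term for
non-self-complementary duplexes:

$$T_m = \frac{1000\,\Delta H}{\Delta S + 0.368(N-1)\ln[\mathrm{Na^+}] + R\ln(C_T/4)} - 273.15$$

with defaults $[\mathrm{Na^+}] = 50$ mM and $C_T = 0.25\,\mu$M. The
parameter set is the published unified table; the test suite checks the
implementation against an independently written second implementation
of the same table to 0.01 °C. When two candidate lengths at one anchor
are equally close to the target the shorter probe wins — a deterministic
tie-break, and shorter oligos synthesize more reliably.

Probes matching the genome more than once (exact match, either strand;
`count_exact_matches()`) are removed before any analysis, since repeated
sequence would otherwise pool signal from multiple loci onto one spot.
Only exact-match uniqueness is screened; near-exact (mismatched) repeat
similarity is out of scope.

## Sliding-window detection and randomization-calibrated thresholds

Detection works on a `signal_table`: probes sorted by position, one
column of log2(ChIP/input) per array. A window of $w$ consecutive
probes qualifies when **every** probe in it is at or above the window's
threshold; overlapping qualifying windows union into one peak spanning
the first to the last probe of the maximal qualifying run. The
all-probes-above rule (rather than window mean) is what makes the
three-window scheme meaningful: windows of 3, 4 and 5 probes with three
different thresholds catch small high peaks as well as broader, lower
ones. The predicate is isolated in one place in the code, so the mean
variant would be a one-line change. Two further rules:

* probes whose starts lie more than `max_probe_gap` = 500 bp apart
  break every window — windows must not span tiling deserts left by
  masked repeats (the choice is ours; the original protocol is silent);
* comparisons are `>=` with no epsilon; values are taken as given.

Thresholds are not fixed a priori. For each window length the detection
is repeated over an increasing grid (0.1 to 4.0 log2 units in 0.1
steps) on the real signals and on a *randomized* copy in which the
array's values are permuted uniformly across probe positions. The
**theoretical FDR** at a threshold is the randomized peak count divided
by the real peak count, and `calibrate_threshold()` returns the
smallest grid threshold whose ratio falls below `fdr_target` = 10%.
One permutation is drawn per calibration (seed-fixed) and reused across
the grid, which keeps the trace comparable along the grid. Permuting
values or permuting probe positions are the same operation when
coordinates are fixed; values are what we permute.

Post-processing follows the protocol: peaks supported by a single probe
are removed, and peaks within `merge_gap` = 1.5 kb (inclusive) are
merged transitively, with probe counts summed, means recomputed
probe-weighted, and the maximum kept. For replicate experiments,
`consensus_peaks()` averages probe values across the named arrays
before detection — a deliberately transparent substitute for
model-based replicate peak callers (hidden-Markov posterior methods),
which are outside this package's scope.

One subtlety the test suite documents: the *number* of peaks is not
monotone in the threshold. Raising a threshold can split one long
qualifying run into two shorter ones, briefly increasing the count.
What is monotone — and what the properties assert — is containment:
every peak at a stricter threshold nests inside a peak at a looser one,
and the total covered territory never grows. Counts are monotone in
window length.

## Assembling a promoter array design

`extend_and_merge()` widens every seed region by `extend` = 2 kb per
side, clips at scaffold bounds, and merges overlapping or touching
results (source tags concatenate, so a merged region remembers whether
it came from a peak, a gene TSS, EST evidence, or several of these).
With isolated narrow seeds the output is therefore ~4 kb long — the
characteristic promoter-region size of this design style.
`tss_regions()` produces the `[tss - 2\,\mathrm{kb}, tss + 2\,\mathrm{kb})`
windows for annotated genes, with strand deciding which gene end is the
TSS. EST-derived TSS clusters are accepted as pre-computed regions —
the clustering method itself is described elsewhere and is not
reimplemented here.

`assemble_design()` merges the three region sets, adds the complete
tile path of any named background scaffolds (for measuring genomic
background in later peak calling), tiles everything with the isothermal
tiler, removes multi-mapping probes, and checks the result against the
probe budget (default 2.1 million, one high-density array). Exceeding
the budget is a classed error carrying the overshoot and a per-source
probe breakdown rather than a silent truncation: the principled way to
shrink a design is to re-call peaks at more stringent thresholds, not
to drop arbitrary regions. Touching regions merge — tile paths should
be contiguous.

## Annotation

* `associate_peaks()` links peaks to genes within 1 kb (inclusive,
  edge-to-edge). Two anchorings are offered because promoter reporting
  uses both: distance to the TSS base, and distance to the full gene
  span. `fraction_near_genes()` reports the associated fraction with
  exact counts attached.
* `overlap_fraction()` counts a peak as detected in a second set when
  they share at least 1 bp (half-open intervals; a boundary case the
  tests pin down).
* `overlap_significance()` is a permutation test: the first peak set is
  re-placed uniformly within its own scaffolds (lengths preserved),
  conditioning on the observed length and scaffold distribution, and
  $p = (1 + \#\{\mathrm{perm} \ge \mathrm{obs}\})/(1 + n_{\mathrm{perm}})$.
  It is a generic substitute for whatever test produced published
  overlap p-values, not a reproduction of one.
* `per_peak_mean_signal()` averages the probes whose midpoints fall
  inside each peak; peaks without probes are flagged `NA` and excluded
  from correlations. `correlate_tracks()` wraps Pearson and Spearman
  correlation with two-sided p-values.
* `tss_profile()` bins probe values by midpoint offset from each gene's
  TSS (minus-strand offsets negated) and averages per-gene bin means
  across genes.
* `link_orphan_scaffolds()` implements the two-criterion EST filter:
  blocks on exactly two scaffolds, and a peak within 1 kb of one of the
  EST's blocks (block edge to peak edge — block edges are the only
  coordinates an alignment defines) on at least one scaffold. Unordered
  scaffold pairs supported by at least two passing ESTs become links.

## The simulator: what it emulates, and what it does not

`sim_params()` defaults describe a small but structurally faithful
study: 4 scaffolds × 100 kb, 40% GC, ~20% repeat-masked, 40
non-overlapping genes with mask-free promoter windows, half of the gene
TSSs carrying a flat enriched plateau of 1 kb, log2-ratio enrichment
mean 2.0 against background noise sd 0.5, two replicate arrays with
additional technical noise sd 0.25 (biological variance between
replicate embryo batches is low in this assay class, and these values
give replicate correlations near 0.9), and 4 planted scaffold pairs
joined by 3 split ESTs each, plus single-, triple- and far-from-peak
decoy ESTs. Enrichment is modeled as a flat plateau with no shoulder
decay — the simplest truth for overlap scoring. Noise is Gaussian on
the log2-ratio scale, since that is the level at which the method
operates; dye bias, spatial artifacts and probe-sequence affinity are
deliberately not modeled. Passing tests on these fixtures demonstrates
that the algorithms recover planted structure under calibrated noise;
they do not certify performance on real arrays, where normalization
quality and probe-level effects dominate.

Everything is a deterministic function of the mandatory seed (the
genome, signal and EST stages use `seed`, `seed + 1`, `seed + 2`).

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so the
full suite completes in a few minutes on one core: the calibration
demonstration uses 2 scaffolds × 50,000 probes with 500 planted 1 kb
regions; detector-versus-oracle checks use 200 random tracks of 8–40
probes; the permutation-test calibration uses 500 null datasets of 300
regions at 100 permutations each; end-to-end recovery runs at the
simulator defaults above. Genome-scale inputs (millions of probes) go
through the same code paths; the sliding-window core is vectorized and
linear in the probe count.

Numerical conventions: intervals are half-open at every file boundary
(BED) and `GRanges` in memory; "within X kb" is always inclusive;
threshold comparisons are exact (`>=`); Tm ties break to the shorter
probe; the calibration grid is fixed rather than adaptive so traces are
reproducible and comparable.

## Known limitations

* Input log2 ratios are taken as already normalized; no normalization
  is applied or checked.
* Probe uniqueness is exact-match only.
* The replicate-consensus caller averages arrays; it does not model
  replicate variance the way HMM-based callers do.
* The union of the three calibrated windows controls each window's
  theoretical FDR at 10% separately, not the FDR of the union; on
  well-separated signal this distinction is immaterial (the empirical
  FDR in the recovery tests is ~0), but on marginal data the union is
  the more permissive set — by design, since the design stage prefers
  inclusive peak sets.
* The permutation placement allows overlaps among permuted peaks, which
  is conservative for dense peak sets.
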