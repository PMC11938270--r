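---
title: "Methods: building and characterising the vole social brain connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and characterising the vole social brain connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

The "vole social brain" is a 15-region network hypothesised to regulate
social behaviours in the prairie vole: the classical social
decision-making network (social behavior network plus mesolimbic reward
system) extended with the anterior cingulate cortex (ACC) and the
paraventricular nucleus of the hypothalamus (PVN). Retrograde tracing
gives a direct handle on its structure: after injecting a retrograde
tracer into region B, labeled somata found in region A mark the
projection A → B. Counting labeled cells per atlas region, on both the
ipsilateral and contralateral side of the injection, yields a directed
weighted graph whose edge weights are cell counts.

This package implements that analysis end to end — per-region cell
counting on slice images, connectome construction, hub and module
analysis, cartographic node classification, and the associated
statistics — together with a synthetic-data generator so every stage can
be validated against known ground truth without tracer imaging data.

## From slice images to counts

A *region label map* is an integer-coded template image: each atlas
region, ipsilateral and contralateral halves separately, carries one
code, with 0 reserved for background. Template fitting is reduced to
applying a user-supplied 2D affine with nearest-neighbour resampling
(`apply_template()`): codes are never blended, and no code absent from
the region table can appear. Interactive per-region template warping, as
done by hand in vector-graphics editors, is deliberately out of scope —
the caller supplies whatever affine their registration produced.

Cells are segmented by thresholding (`segment_cells()`): either a fixed
grey value, or Otsu's method on a 256-bin histogram in automatic mode.
Foreground is labeled with 8-connectivity, and components with pixel
area inside `[min_area_px, max_area_px]` are retained. There is no
watershed splitting: touching cells merge into one component and are
under-counted, a documented limitation. Each object is assigned to the
region under its *centroid* (point-like somata make this cheap and
deterministic; majority-pixel voting would differ only for objects
straddling a boundary), and objects whose centroid lands on background
are dropped but reported, so counts are conserved.

Regions in which more than `saturation_fraction_limit` (default 0.5) of
pixels sit at the dtype maximum are flagged: their counts are reported
but marked unreliable, operationalising the exclusion of slices whose
label is too intense for automated counting. `concordance()` scores
automated against manual counts as
`100 × (1 − Σ|auto − manual| / Σ manual)` over unflagged regions, with
the conventions that two all-zero tables agree at 100% and a zero manual
total with nonzero automated counts agrees at 0%.

When sections of thickness *t* are collected every *i* micrometres, the
counted fraction of each region is *t/i*
(`series_sampling_fraction()`); 30 µm sections at a 180 µm interval
sample 1/6 ≈ 16.67%.

## The connectome and its descriptors

`build_connectome()` applies the retrograde convention — a count row
(injection = B, source = A, count c) contributes weight c to edge
A → B — summing ipsilateral and contralateral counts into the edge
weight while retaining both as edge attributes. Ordered pairs with total
count 0 carry *no* edge, so unweighted degree counts actual projections.
Dyad classification labels each of the n(n−1) ordered pairs as
bidirectional, unidirectional or absent; on 15 regions the three classes
always partition the 210 possible directed combinations.

For display, edge counts are mapped linearly onto [0, 0.9]
(`scale_edge_weights()`): the heaviest edge gets 0.9 and the mapping is
monotone. Only the output range is fixed by convention; linear
max-normalisation is the minimal assumption and is isolated in one
function so it can be swapped.

## Modules, WMDz, PC and cartography

Each node's *projection profile* is the concatenation of its afferent
and efferent count vectors over all other nodes (ipsi + contra summed).
Modules are flat cuts of an agglomerative hierarchical clustering of
these profiles under Euclidean distance (`detect_modules()`), cut at a
height or into k clusters. The linkage is complete by default —
deterministic and standard with fixed-height cuts — with average and
Ward linkage available. Cut heights (such as the 1100 / 1700 values used
for real vole trees) are data-specific settings, not constants of the
method.

The **within-module degree Z-score** standardises a node's
within-module strength against its module peers:
z_i = (k_i − mean_s) / sd_s, where k_i sums the weights of node i's in-
and out-edges to same-module nodes. The SD is the *population* SD
(divisor n), the Brain Connectivity Toolbox convention; a sample-SD
variant is available via `sample_sd = TRUE`. A node alone in its module
has WMDz 0 by definition, and a zero-variance module yields 0 for all
members (the z-score is undefined there; 0 is the neutral choice).

The **participation coefficient** is
PC_i = 1 − Σ_s (K_is / k_i)², summing over *all* modules including the
node's own, with K_is the weight of i's edges to module s and k_i its
total strength. Edge direction is ignored here (in + out summed): "all
edges connected to node i" is direction-free, and a directed in/out
variant is exposed separately
(`participation_coefficient_directed()`). A node with no edges has
PC 0. PC is scale-invariant under uniform weight scaling, so raw counts
are used rather than display weights (per-graph max-normalisation would
otherwise make PC depend on an unrelated edge).

Hub analysis ranks nodes by total degree (unweighted) or total strength
(weighted); the top node is the proposed hub, and ties are reported as
co-hubs rather than broken silently. Cartographic classification uses
the classical role boundaries on PC: peripheral below 0.625, non-hub
connector in [0.625, 0.8), connector at 0.8 and above, with half-open
intervals fixing the boundary at 0.625 (published variants of these
bands overlap at the second decimal). The degree-based side conditions
("fewer than 4 links") that accompany these bands in the unweighted
setting are not enforced: with weighted strengths in the thousands they
are not meaningful, a documented deviation. A node whose module is a
singleton is an *isolate* regardless of PC — in the real network this is
the anterior hypothalamus, which is simultaneously the weighted hub.

`efferent_hub_analysis()` extends the hub question to regions outside
the core network: for each external source region, the *edge count*
(how many core regions it reaches) and the *weighted edge count* (summed
cell counts), each ranked.

## Statistics

Ipsi-vs-contra and afferent-vs-efferent comparisons use the Student
(equal-variance) unpaired t-test — Welch's form is a flag — with the
degenerate-variance conventions t = 0, p = 1 for equal means and p = 0
otherwise. Across-region comparisons use fixed-effects one-way ANOVA
(F with k−1, N−k degrees of freedom; 15 groups of 3 replicates give
F(14, 30)), followed when significant by all pairwise t comparisons with
Bonferroni correction: p multiplied by the number of pairs (C(15,2) =
105 for the full region set) and capped at 1. Selecting three replicate
brains per region at random is reproduced as seeded subsampling
(`subsample_brains()`). The default significance level is 0.05.

## The synthetic generator

`generate_count_matrix()` emulates the *structure* of tracer count
tables, not their biology:

* **Modularity.** Directed edges between same-module regions draw their
  mean from `mean_within` (default 100), between-module edges from
  `mean_between` (default 10). The default assignment is three equal
  modules of five.
* **Hub inflation.** An optional hub node has all incident edge means
  multiplied by `hub_boost` (default 1.5) — strong enough that the hub
  tops the strength ranking, mild enough that it stays inside its
  planted module rather than splitting off the dendrogram.
* **Ipsi ≫ contra.** Each total count is split binomially with
  contralateral probability `contra_fraction` = 0.15 — a deliberately
  qualitative encoding of the strong ipsilateral bias of tracer counts,
  not a claim about the real ratio.
* **Overdispersion.** Counts are negative-binomial with size
  `dispersion` (default 10, i.e. variance ≈ µ + µ²/10); `Inf` requests
  the Poisson limit. Real per-brain count dispersion is unreported, so
  the default is a plausible moderate choice, not a calibration.
* **Density.** Ordered pairs carry a record with probability
  `edge_density` = 0.976, matching a network in which 205 of 210
  directed combinations are connected.

Identical seeds give identical tables, and the caller's RNG state is
restored. Ground truth (module assignment, hub) is always returned as a
sidecar, never encoded in the data.

`generate_slice_image()` renders per-region ground truth for the
imaging stage: disk-shaped cells (radius 3 px by default) at a fixed
intensity over Gaussian background noise, placed by rejection sampling
(cap 1000 attempts per cell) with centres at least 2r + 2 px apart so
rendered cells remain separable components; overlap is only allowed via
an explicit flag for stress-testing. Saturated regions are filled at
65535. The generator does not model microscope optics, PSF blur,
stitching seams, or realistic region shapes — so passing recovery tests
show the counting machinery is exact on well-separated point-like
signal, not that it matches any particular microscope's error profile.

## Validation design and problem sizes

The test suite validates each stage against independent oracles: dyad
classification against brute-force enumeration over ordered pairs; WMDz
and PC against literal per-node evaluation of their formulas,
exhaustively over every weighted digraph on up to 4 nodes with weights
in {0, 1, 2} (all set partitions at n ≤ 3; two representative
partitions, one containing a singleton module, at n = 4, where the
oracle is an independent vectorised evaluation); module and hub
recovery on 100 seeded count matrices with three planted modules,
within/between mean ratio 10 and low overdispersion (negative-binomial
size 100, the "low noise" end of the generator's range); and imaging
recovery on 100 seeded slices with cell intensity 145 noise-SDs above
background, where per-region counts must equal ground truth in at least
99. These sizes keep the full suite within a few minutes while leaving
each check exhaustive or statistically strict.

## Known limitations

* Merged (touching) cells are counted once; no splitting is attempted.
* Centroid assignment can misattribute an object straddling a region
  boundary.
* The affine template fit cannot express the local, per-region warps a
  human expert applies; residual misregistration becomes counting error.
* Module detection is a dendrogram cut, not modularity optimisation;
  the number/height of the cut is the analyst's choice.
* The generator's defaults describe a plausible tracer experiment, not
  a fitted model of any particular dataset.
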