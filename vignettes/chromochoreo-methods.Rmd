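---
title: "Models and methods behind chromochoreo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromochoreo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromochoreo)
```

`chromochoreo` quantifies the cell-cycle choreography of bacteria with
multipartite genomes: where origin, terminus and division-protein signals
sit along the cell, and when each locus duplicates. This vignette explains
the models, the tunable parameters, the synthetic-data generators the test
suite is built on, and the design decisions that were genuinely open.

## The age-distribution timing model

The central estimator converts a population snapshot into a duplication
time. Its only modelling assumption is steady-state exponential growth: in
such a population the density of cell ages $a \in [0,1]$ (fraction of the
cycle elapsed) is

$$p(a) = 2\ln 2\; 2^{-a}, \qquad F(a) = 2\,(1 - 2^{-a}),$$

so newborn cells are twice as frequent as cells about to divide. If a
locus duplicates at age $a_d$ and replication rounds do not overlap (every
cell shows one or two foci), the fraction of cells with a single focus is
$F = 2(1-2^{-a_d})$, and inversion gives

$$a_d = -\frac{\ln(1 - F/2)}{\ln 2}, \qquad t_d = a_d \, T,$$

with $T$ the generation time (default 150 min, always overridable). Cells
showing zero or more than two foci are excluded from $F$ and their count
reported — they are real (out-of-focus, failed tags, unclassifiable
signal) but carry no timing information under this model.

Uncertainty: the 95% interval on $t_d$ is the Wilson score interval of the
binomial count mapped through the age formula. Because the map is strictly
monotone this is exact — no delta-method linearisation — and it inherits
the good small-sample behaviour of the Wilson interval.

The test suite verifies the inverse relation to $10^{-12}$, and recovers
planted duplication ages from simulated populations ($n = 5000$ cells,
200 replicates per age on a grid $\{0.2, 0.5, 0.8\}$) with absolute bias
below 0.02 and $\ge 90\%$ interval coverage.

`segregation_report()` orders per-locus estimates and differences matched
Ori/Ter pairs (matched on the trailing replicon identifier), giving the
apparent time each replicon spends replicating/cohesed.

## Genome-feature operations

**Cumulative GC skew.** Per window, skew is $(G - C)/(G + C)$ (0 for
windows without G or C; `N` bases count in neither term); the cumulative
curve is its running sum from position 1, following the convention of the
common skew-plotting tools of fixing the published sequence start. On
bidirectionally replicated circular chromosomes the curve's global minimum
marks the origin and its global maximum the terminus. The default window
is 1 bp: extrema of the cumulative curve are robust to windowing (a test
checks a 1-bp vs 500-bp window agree on a strongly skewed synthetic
genome), so finer resolution costs nothing but memory. Ties break toward
the smallest coordinate, recorded in the result; constant profiles return
a flagged no-extremum result rather than coordinates.

**parS-candidate palindromes.** Centromere-like *parS* sites are inverted
repeats bound symmetrically by ParB, so the search looks for maximal
even-length substrings equal to their own reverse complement with at most
`max_mismatch` mismatched pairs (default 0; "nearly perfect" candidates
use 2 — no published criterion fixes this number, so it is exposed).
Reported hits always begin and end on a complementary pair: a hit with
frayed mismatched ends is biologically meaningless, and adopting the
convention uniformly keeps the implementation provably equal to the
brute-force enumeration oracle it is tested against (all sequences up to
2 kb). Maximality is global: a hit properly contained in a longer
qualifying hit is dropped.

**Degenerate consensus motifs.** IUPAC patterns are matched through
Biostrings with a literal subject: an `N` in the genome never satisfies a
literal pattern base but does satisfy pattern wildcards. Minus-strand hits
are matches of the reverse-complemented pattern reported in forward
coordinates. Circular replicons are handled by virtual extension with the
first `pattern length − 1` bases; an origin-spanning hit is reported with
`start` normalised to $[1, L]$ and `end = start + width − 1`, which may
exceed $L$. The alternative — clamping `end` to $L$ — would break the
rotation-invariance of hit counts that the tests enforce, so wrapping
coordinates won.

**KOPS strand bias.** FtsK-orienting sequences point toward the terminus
on each replichore's leading strand, so their majority strand flips
between the two ori→ter arcs. Hits are assigned to arcs by circular
midpoint; each arc's strand split is tested against 0.5 with an exact
binomial test and the inversion verdict requires both the flip and
significance at a configurable `alpha` (default 0.05). On replichore-skewed
synthetic genomes the inversion emerges from composition alone: the KOPS
consensus is G-rich, so the G-rich leading strand carries nearly all hits.

**Replicon-unique filtering** keeps candidates whose exact sequence (either
strand) is absent from every other replicon and whose midpoint lies within
`ori_window_bp` of the origin (default 10 kb — secondary-chromosome *parS*
candidates cluster within a few kb of their origin). The operation is a
subset filter and idempotent.

**Percent identity** uses global Needleman–Wunsch alignment (BLOSUM62, gap
open 10, extension 0.5) and counts identical pairs over alignment columns
excluding terminal gaps. Different aligners divide by slightly different
denominators; the parameters are exposed rather than hidden.

## Image quantification

The quantification chain is designed for sparse, synthetic-grade frames —
single cells or well-separated groups — and is explicitly not a
general-purpose segmentation suite for crowded micrographs.

* **Segmentation**: Gaussian smoothing, Otsu threshold, connected
  components. Intensities are clipped at the 0.9 quantile before
  thresholding so that bright diffraction-limited foci cannot dominate the
  Otsu split; the threshold then separates cell body from background. A
  frame whose "foreground" does not exceed the background by
  `min_contrast_k` background MADs (default 4) is declared empty, which
  keeps pure-noise frames from segmenting into speckle. Regions wider than
  `max_width_um` (default 1.6 µm) are flagged ambiguous — almost always
  touching cells merged into one component — and excluded from statistics.
  The medial axis is the principal axis of the pixel cloud; length and
  width are extents along and across it.
* **Focus detection**: local maxima above
  `baseline + max(k·MAD, min_amplitude)` (baseline = in-mask median, noise
  from out-of-mask pixels, `k = 5`), non-maximum suppression at 3 px,
  at most `max_foci` kept strongest-first, then subpixel refinement by a
  background-subtracted centroid in a 7×7 window. A Gaussian fit would add
  precision only below the 0.5-px level the round-trip tests already meet
  at synthetic signal-to-noise, so the centroid was kept. Saturated
  plateaus collapse to their centroid and are flagged.
* **Pole orientation** is unknowable from a snapshot (distinguishing new
  from old pole needs time-lapse), so axis orientation is fixed
  deterministically (positive x) and population analyses should fold
  positions to $[0, 0.5]$ when the sign is arbitrary.
* **Interfocal distance** is Euclidean by default with an `"axial"` option;
  published IFD values rarely state which convention was used, and on
  near-axial foci the two differ by less than a pixel.
* **Ring detection (2D)**: a septal ring appears as a transverse band; the
  axial profile (mean in-mask intensity per column) must exceed
  `k = 1.5` times its median, and — to reject bright foci, which also bump
  the axial profile — the signal at the band's peak column must cover most
  of the cell width (`coverage_min = 0.6`). A focus covers only
  $\sim 2\sigma_{\mathrm{PSF}}$ of the width and fails the coverage test.
* **Ring diameter (3D)**: maximum-intensity projection along the cell
  axis, intensity-weighted algebraic (Kåsa) circle fit to above-threshold
  pixels in physical coordinates (lateral pixel and z-step differ), then
  radius refinement as the intensity-weighted mean radial distance from
  the fitted centre. An earlier histogram-based ridge estimate proved
  fragile against the coarse 125-nm z-sampling; the weighted mean is
  exact for the symmetric blurred annulus and recovers planted diameters
  across a 0.1–0.8 µm sweep within 2 pixels, monotonically.
* **Colocalization** pairs foci across channels under a distance
  threshold. The implementation maximises the number of matches and then
  minimises total distance by exhaustive assignment — per-cell focus
  counts are tiny, so this is cheap. A greedy nearest-pair heuristic is
  available (`method = "greedy"`) but provably suboptimal: one close pair
  can starve two feasible matches, a configuration the tests include.
* **Demographs** stack min–max-normalised axial profiles of cells sorted
  by length; `(x - \min)/(\max - \min)` uses the lowest intensity as the
  background reference and the highest as full scale, and constant
  profiles are flagged rather than divided by zero.
* **Constriction phases**: ring diameter vs cell length is fitted with a
  continuous flat-then-linear model by exhaustive least squares over
  candidate changepoints at the observed lengths; the scan *is* the
  method (50 points → 44 closed-form fits), and a test pins it to an
  independent `lm()`-based scan. The fit is flagged degenerate when the
  implied diameter drop over the constriction segment is below
  `min_drop_um` (default 0.1 µm) — a scale-aware criterion, unlike a raw
  slope cutoff, which noise on a short terminal segment can exceed.
  Noise-free changepoint error is bounded by the spacing of observed
  lengths around the true changepoint, and the tests assert exactly that.

## The synthetic-data generators

The generators define the study conditions the package is validated under.

* **Ages** are drawn by inverse-CDF sampling from $p(a)$ above; a
  Kolmogorov–Smirnov check at $n = 10^5$ holds the empirical CDF within
  0.01 of the closed form.
* **Populations**: length interpolates linearly from 1.7 µm at birth to
  3.4 µm at division — elongation kinetics are not specified by the
  snapshot model, only the age→length ordering matters downstream, and
  the defaults bracket the 1.7–2.5 µm "small two-focus cell" class while
  keeping division at twice birth length. Both are configurable. Each
  locus shows its pre-duplication positions before $a_d$ and its
  post-duplication pair after, with Gaussian positional noise (SD 0.02–
  0.03 of cell length) clipped to $[0,1]$. An optional septal-ring program
  adds a midcell ring from an onset age, with a flat-then-constricting
  diameter against length.
* **Genomes** are circular with 1-based inclusive coordinates. On the
  leading strand from ori to ter, $P(G) = 0.25 + s$ and
  $P(C) = 0.25 - s$ (default $s = 0.15$); the bias reverses on the other
  replichore; A and T stay at 0.25 since GC skew is the only statistic
  consumed. Planted motifs overwrite the background (reverse-complemented
  on the minus strand) and must not overlap.
* **Images**: cells are capped rectangles on a horizontal medial axis;
  foci are 2D Gaussians of PSF width $\sigma = 0.1$ µm at 0.064 µm/px
  (both configurable, never hard-coded); septal rings are transverse
  Gaussian bands; z-stacks sample a blurred annulus in the transverse
  plane into 125-nm sections. Noise is additive Gaussian — shot-noise
  realism is unnecessary for validating detector-free geometry — and
  rendering conserves planted focus photons within 1% (tested against the
  analytic Gaussian mass). Identical seeds give bit-identical output.

What the generators deliberately do **not** emulate: photophysics
(bleaching, blinking), structured-illumination stripe artefacts,
phase-contrast/DIC imaging, crowded colonies, cell curvature or branching,
and time-lapse lineages. Green round-trip tests therefore demonstrate the
correctness of the measurement chain, not its robustness to every property
of real micrographs; the segmentation defaults in particular are tuned to
synthetic frames and say nothing about dense real fields of cells.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → features → quantify → timing → report
from one nested configuration (YAML/JSON or `default_config()`), validated
against a schema that rejects unknown keys by name. A single top-level
seed is hashed with each stage name into per-stage substreams, so adding a
stage never perturbs earlier stages' draws; re-running an identical
configuration reproduces byte-identical CSV/JSON outputs (tested via file
digests). The manifest records package version, seed, per-stage status and
MD5 digests of every output. On-disk genomic intervals are BED 0-based
half-open; all in-memory and report coordinates are 1-based inclusive, and
the conversion lives in a single boundary helper.

The default demonstration population is two origin-like channels — a
sub-polar early-duplicating locus ($a_d = 0.19$, positions 15%/85% of cell
length) and a symmetric later one ($a_d = 0.28$, 30%/70%) — plus the
septal-ring program; the test suite runs it at 40–200 quantified cells,
which keeps the full suite around a minute while leaving every stage
exercised. In the pipeline, ring presence and position are measured on the
2D frames, and each ringed cell's diameter is measured by rendering and
fitting its ring z-stack; the constriction fit then uses those measured
diameters against measured lengths.

## Known limitations

* The timing model assumes non-overlapping replication rounds; fast-growing
  populations with multifork replication need a different focus-count
  model.
* Ori/Ter location by GC skew gives window-midpoint resolution and can be
  displaced by horizontally acquired composition anomalies on real
  genomes.
* The localization-category schemes implement fixed zone thresholds
  (polar 0.2, midcell 0.15 of cell length); published category drawings
  rarely define these zones, so both are configuration parameters, and
  category fractions shift smoothly with them.
* Percent identity depends on alignment parameters at the few-percent
  level; comparisons across tools should fix matrix and gap costs.
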