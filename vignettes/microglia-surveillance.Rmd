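---
title: "Quantifying microglial morphology and surveillance from two-photon time-lapse imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial morphology and surveillance from two-photon time-lapse imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsurv)
```

## The measurement problem

Retinal microglia are ramified immune cells that continuously extend and
retract their processes to survey the surrounding tissue. Under chronic
hyperglycemia their phenotype shifts: the soma enlarges, the arbor (the
territory spanned by the processes) shrinks, and — visible only in live
imaging — the process tips move farther and faster, with retraction speed
affected more than extension. GLP-1 receptor agonists such as liraglutide
suppress this heightened surveillance without lowering blood glucose in a
beta-cell-ablated model.

Quantifying this phenotype from in vivo two-photon recordings is classically
a manual workflow: rigid motion correction against the vessel channel,
maximum-intensity projections (MIPs) over consecutive scans, wand-tool soma
outlines, polygon tools for territories, neurite tracing for process
lengths, and manual tip tracking. `microsurv` automates that workflow as a
tested pipeline and pairs it with a synthetic two-channel generator whose
ground truth makes every stage verifiable without microscope data.

## Pipeline model

The input is a two-channel time series: channel 1 blood vessels (a static
structure up to motion), channel 2 microglia. The reference protocol scans
one frame every 4 s for 10 min (150 frames); frames are 1,024 x 1,024
pixels in vivo and 256-384 pixels here (the analysis is resolution-aware
via the pixel size, so the scale is configuration, not assumption).

1. **Registration** (`register_series`). Motion is modelled as a per-frame
   lateral translation, matching how such recordings are corrected in
   practice (rigid XY registration against an average vessel image). Each
   vessel frame is aligned to the pixel-wise mean vessel image by FFT
   cross-correlation over integer displacements, refined to sub-pixel
   precision by a quadratic fit of the correlation peak in each axis; the
   negated shift is applied to both channels with a single bilinear
   interpolation. A per-frame confidence (correlation at the optimum) flags
   uninformative frames; constant frames yield shift (0, 0) with confidence
   0 rather than a silent result. Because the reference is the average of
   the (shifted) frames, the registered series is aligned up to one global
   constant; residuals are therefore assessed after removing their mean.
2. **MIP series** (`build_mip_series`). Non-overlapping windows of 5
   consecutive registered frames (20 s of scanning) each yield one
   pixel-wise maximum projection: 30 MIP time points per 10-min session.
   Temporal block averaging over the same windows is available as its own
   operation (`temporal_average`); the morphometry runs on the MIPs, which
   keep thin moving processes visible that averaging would blur. A trailing
   partial window is dropped.
3. **Static morphometry** (`measure_mip`). Soma seeds are detected by
   opening away thin ridges and keeping bright blobs (somata are the
   brightest structures in the channel; blobs below half the brightest
   blob's peak-to-background range are rejected as swept process segments).
   Each soma is segmented by tolerance-based region growing — the wand-tool
   formalised — with the cutoff at `background + (1 - tolerance) * (peak -
   background)`. The default tolerance of 0.5 is the half-maximum level
   set: for a symmetric edge profile it recovers the true boundary without
   bias, whereas a tighter tolerance under-segments soft-edged somata by
   about a pixel of radius (a 10-25% area error at realistic 3-4 um somata).
   The per-cell foreground is cut at 20% of the soma peak-to-background
   range inside a window around the soma (anchoring the cut to each cell's
   brightness keeps the dimmer process ridges, which a window Otsu cut —
   dominated by the bright soma mode — drops), restricted to pixels nearer
   this soma than any neighbouring one, and thinned to a one-pixel skeleton
   (Guo-Hall; Zhang-Suen erases two-pixel diagonal strips, which
   curvilinear processes frequently produce). The skeleton decomposes into
   chains between junctions and endpoints; spur chains shorter than 2 um
   are pruned. Lengths are measured on moving-average-smoothed pixel
   chains, because raw 8-connected chain codes overestimate oblique
   straight segments by up to ~8%; smoothing is orientation-unbiased.
   Endpoint erosion by thinning is corrected by marching each tip forward
   to the foreground contour along its local direction — for a stroke whose
   intensity is the line integral of its cross-section, the half-level
   contour closes essentially at the true stroke endpoint. The reported
   metrics per cell: soma area, territory area (the polygon over all distal
   tips, ordered by polar angle about the soma centroid, area by the
   shoelace formula), primary process lengths (soma boundary to first
   branch point), total process length (sum of all chain lengths), and tip
   coordinates. Cells touching the field border are excluded and counted.
4. **Dynamics** (`cell_dynamics_table`). Tips are linked across MIP time
   points per cell by mutual nearest neighbour under a 10 um gate per 20-s
   interval (a brute-force assignment oracle backs this in the tests);
   detection dropouts are bridged across up to 2 missing time points under
   a proportionally scaled gate. Per cell, the pipeline reports the
   cumulative absolute change of soma area and of territory area, and —
   averaged over tracks spanning at least half the session — the cumulative
   tip movement distance, the surveillance territory area (convex hull of
   the track), and extension/retraction speeds. Speeds classify each
   interval by the change in tip-to-soma-centroid distance with a 0.2 um
   stationary band against localisation jitter, and average |dr|/dt within
   each class (um/min). The soma centroid is the time-median position,
   so soma drift is not counted as process motion.
5. **Statistics** (`compare_two_groups`, `compare_multi_groups`). The route
   is decided per sample: Shapiro-Wilk at alpha = 0.05 for n <= 30; for
   larger samples the parametric route is taken unless |skewness| >= 2 or
   |excess kurtosis| >= 4 (an automated stand-in for visual Q-Q
   inspection, thresholds configurable and recorded). Parametric: Welch's
   t test, or one-way ANOVA with Bonferroni-corrected pairwise tests.
   Nonparametric: Mann-Whitney U, or Kruskal-Wallis with Dunn's test under
   Bonferroni correction. Matched designs use Friedman with Conover's test.
   Every comparison reports means +/- SEM, the route taken and its
   diagnostics. Cells are the analysis unit, matching the reference
   protocol's per-cell n; animal-level clustering is deliberately not
   modelled, and outputs record that choice.

## The synthetic generator

`generate_fov_series` renders two channels: a static vessel map (smooth
random curvilinear strokes) and microglia as soft-edged soma disks plus
straight process strokes from soma to tip, with Gaussian cross-sections
(0.8 um sd). Noise follows the detector model `counts =
Poisson(photon_gain * signal) + offset + N(0, read_sd)`, and a per-frame
lateral translation — drawn from N(0, motion_amplitude^2) or injected
explicitly — is applied identically to both channels before noise.

Tips perform a biased persistent random walk: an isotropic Gaussian step
per 4-s frame (`tip_step_sd`), an optional radial drift (`extension_bias`),
and a gain on inward-pointing steps (`retraction_speed_gain`) that creates
the extension/retraction asymmetry. Tips reflect off the soma and off the
territory radius, and tips of one cell are kept at least 0.4 rad apart in
angle: processes of a single cell are distinct structures that do not fuse,
and without that constraint two near-collinear strokes merge in the
rendering, making the measured tip count flicker — an artifact of the 2-D
projection, not of the biology being modelled. Soma area performs a bounded
random walk (`soma_pulsation_amp`) so its cumulative change is nonzero in
every condition. Cells are placed on a jittered grid with a minimum
separation of 1.8 territory radii; a field too small for the requested
cell count is an explicit placement-overflow error, never a silent overlap.

The condition presets encode the in vivo orderings; their absolute values
are model configuration chosen once so that each programmed effect is
detectable at 30-50 cells per arm, the per-group cell counts of the
reference protocol:

| preset | soma radius (um) | process length (um) | territory (um) | tip step sd (um/frame) | retraction gain |
|---|---|---|---|---|---|
| control | 3.0 | 16 | 20 | 0.35 | 1.0 |
| diabetic | 3.9 | 11 | 14 | 1.00 | 1.6 |
| liraglutide | 3.8 | 12 | 15 | 0.30 | 1.0 |
| lps | 3.5 | 13 | 16 | 0.95 | 1.5 |

Two notes on these choices. The diabetic tip step is set well above
control's because the cumulative territory-area change scales with the
product of arbor radius and tip step: the diabetic arbor is programmed
smaller, so a merely moderate step increase would leave its absolute
area fluctuation at or below control's, contradicting the phenotype the
preset must encode. The liraglutide preset keeps diabetic morphology
(large soma, short arbor) while motility drops to or below control —
surveillance is suppressed without reversing the static morphology within
the session.

What the generator does not emulate: 3-D structure (a single optical
section is rendered), photobleaching, vessel pulsation, process branching
in the generated cells (branch handling is tested on constructed
geometry), ameboid/macrophage morphologies, and layer stratification.
Passing the end-to-end tests therefore shows that the pipeline recovers
programmed morphodynamic contrasts from realistic noise, motion and
rendering — not that it handles every morphology real retinas present.

## Resolution estimation

`compute_fwhm` measures the full width at half maximum of an intensity
profile (line or point spread): background is the profile minimum, the
peak height comes from a local quadratic fit guarded by the raw maximum
(unbiased under sampling noise, exact on plateaus), and the two half-level
crossings are located by linear interpolation. The estimate is invariant
to intensity scaling and constant offsets; a Gaussian-fit mode is
available. `profile_line` extracts calibrated profiles from images.

## Numerical choices and degenerate inputs

* Coordinates are 0-based physical (x = column, y = row, origin at the
  top-left pixel centre), all outputs in um via the pixel size.
* Registration search radius 20 px; sub-pixel refinement capped at half a
  pixel; out-of-frame pixels filled with the frame median and the maximal
  border flagged so morphometry ignores it.
* Territory polygons with fewer than 3 tips or collinear tips have area 0
  with a degeneracy flag, as do degenerate convex hulls.
* Tracks with a single point yield NA metrics with a warning; a speed
  class with no intervals is NA, excluded from cell averages.
* Identical zero-variance groups compare at p = 1 with a degeneracy flag.
* All simulations are bit-reproducible given (spec, preset, noise, seed);
  the RNG state of the caller is saved and restored.

## Problem sizes used in validation

The test-scale study uses 384 x 384 um fields at 1 um/pixel, 40 cells per
arm, 150 frames (30 MIP time points) and 5 replicate seeds per condition —
the per-arm cell count and session structure of the reference protocol at
a desk-scale field. Registration recovery uses 150 frames at 256 x 256
with injected uniform +/-5 px translations. Oracle checks (shoelace vs
rasterisation, hull vs monotone chain, Rayleigh-mean walks) use 100-200
random instances each.

## Known limitations

* Translation-only registration: rotation or non-rigid warps are out of
  scope by design (the correction model is lateral XY displacement).
* The measured territory at a MIP time point reflects the 20-s swept
  envelope of the arbor, so absolute territories are slightly inflated
  relative to an instantaneous snapshot; group contrasts are unaffected.
* Extension/retraction speeds are a radial operationalisation (change in
  tip-to-centroid distance); a path-length-based definition would give
  different absolute values. The stationary band, gate and cadence are
  configuration.
* Per-cell averages treat cells as independent; animal-level random
  effects are intentionally not modelled.
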