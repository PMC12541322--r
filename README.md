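# microsurv

Automated quantification of microglial morphology and process surveillance
from two-channel (blood vessel + microglia) two-photon time-lapse
recordings, with a ground-truth synthetic generator for end-to-end
validation.

Retinal microglia survey their environment by continuously moving their
process tips. Live imaging shows that this surveillance is *enhanced* in
diabetic retinas — larger somata, smaller process arbors, longer tip
trajectories, faster retraction — and that the GLP-1 receptor agonist
liraglutide suppresses the heightened motility. Measuring this phenotype
from in vivo recordings is classically a chain of manual ImageJ steps;
`microsurv` implements that chain as a reproducible pipeline for anyone
quantifying microglial (or comparable ramified-cell) morphodynamics in
time-lapse fluorescence data.

## The measurements

For a registered 10-min session (one frame / 4 s; maximum-intensity
projections over 5-frame windows, i.e. one MIP per 20 s):

**Static, per cell at one MIP** — cell density per field; soma area
(tolerance-based "wand" region growing, cutoff at the half-maximum level
set); territory area: the polygon over all distal tips *t_i* ordered by
polar angle about the soma centroid, with the shoelace area
½|Σ (x_i·y_{i+1} − x_{i+1}·y_i)|; primary process length (soma boundary to
first branch point along the skeleton); total process length (sum of all
skeleton chain lengths).

**Dynamic, per cell over the session** — cumulative absolute change
Σ_t |x(t+1) − x(t)| of soma area and of territory area; cumulative tip
movement distance Σ_t ‖p(t+1) − p(t)‖; surveillance territory area (convex
hull of a tip's trajectory); extension and retraction speeds: per 20-s
interval the change dr in tip-to-soma distance classifies the move
(|dr| > 0.2 µm), and speeds are mean |dr|/dt in µm/min. Per-tip values are
averaged to one value per cell.

**Statistics** — the group-comparison decision tree used in this field:
Shapiro–Wilk routing at n ≤ 30 (moment thresholds above), then Welch's
*t* / Mann–Whitney U for two groups, ANOVA + Bonferroni or Kruskal–Wallis +
Dunn (Bonferroni) for several, Friedman + Conover for matched designs;
everything reported as mean ± SEM with the route recorded.

The synthetic generator renders both channels with Poisson + read noise
and a rigid lateral motion artifact, under condition presets (`control`,
`diabetic`, `liraglutide`, `lps`) that encode the in vivo effect
directions, and exports full ground truth (injected shifts, soma areas,
tip paths) for oracle testing.

## Worked example

```r
library(microsurv)

spec <- acquisition_spec(frame_shape = c(256, 256), pixel_size = 1,
                         frame_interval = 4, duration = 120)
sim <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                           n_cells = 7, seed = 42)
res <- analyze_stack(sim$stack, pipeline_config())
head(res$cells[, c("cell", "soma_area_um2", "territory_area_um2",
                   "total_length_um", "tip_distance_um", "retraction_um_min")])
```

```
  cell soma_area_um2 territory_area_um2 total_length_um tip_distance_um retraction_um_min
1    1            35           761.0054        74.29176        5.590554          2.351278
2    2            26           583.5369        57.94676        4.101772          2.555373
3    3            30           774.4609        85.91686        5.643059          2.526896
4    4            26           702.8545        62.49030        4.151079          1.540222
5    5            41           648.8365        57.94693        6.255957          2.463351
6    6            30           759.3122        86.01284        6.362074          2.823345
```

Each row is one cell: soma area and territory area in µm², total skeleton
length in µm, then the dynamic metrics over this (2-min) demo session —
cumulative tip movement in µm and mean retraction speed in µm/min. A
two-condition comparison:

```r
cells <- run_study(conditions = c("control", "diabetic"), n_cells = 40,
                   n_seeds = 1, base_seed = 1)
compare_two_groups(cells$tip_distance_um[cells$condition == "control"],
                   cells$tip_distance_um[cells$condition == "diabetic"],
                   labels = c("control", "diabetic"))
```

```
Welch t: control 31 +/- 0.274 (n=40) vs diabetic 56.1 +/- 1.91 (n=36)
  statistic = -13.02, p = 2.847e-15, route = parametric
```

Diabetic-preset cells move their tips roughly twice as far over 10 min —
the programmed surveillance enhancement, recovered by the full measurement
chain (registration → MIP → skeleton → tracking) rather than read from the
generator's truth.

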