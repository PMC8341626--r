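# negcontrast

Quantification toolkit for **negative-contrast intravital microscopy**:
fluorescence imaging in which routinely injected vascular/lymphatic tracers
(fluorescent dextrans, Evans blue) perfuse the interstitial space of bone
marrow or lymph node, so that *unlabeled* cells appear as dark objects
against a bright dye-filled background. One fluorescence channel then
encodes the whole cellular landscape — positions, sizes, packing density,
motility, and the dark silhouettes of red blood cells moving through
vessels.

The package is aimed at microscopists and image analysts who want to turn
such single-channel stacks and video-rate series into numbers.

## What it computes

* **Preprocessing** — LUT inversion (`out = 2^bits − 1 − in`), percentile
  contrast enhancement, robust background estimation, vessel-signal
  removal, bone/vessel/low-signal exclusion masks.
* **Cell census** — marker-controlled watershed detection of dark cells
  (2D per section, or direct 3D with anisotropy-aware smoothing; h-minima
  markers, deterministic flooding), a sphere-packing model linking 2D
  sections into 3D cell records (`d = 2·sqrt(A_max/π)`), density per
  µm³ and per standard 100×100×20 µm³ ROI, diameter histograms and the
  sub-10-µm fraction, per-cell mean intensities.
* **Distance statistics** — exact anisotropic Euclidean distance
  transform; distance from each centroid to the nearest blood-vessel
  wall; uniform random-dot reference distributions.
* **Blood-flow velocimetry** — temporal averaging, vessel segmentation,
  Zhang–Suen skeletonization, Hough selection of straight vessel
  segments, digital line scanning into kymographs (rows = time,
  columns = arc position), Radon-transform stripe-angle estimation
  (`speed = tan(angle)·Δs/Δt`, signed along the segment orientation),
  rolling velocity time courses, whole-network flow maps with censoring
  at the reportable bound `v_max = L·fps/min_rows`.
* **Motion & photobleaching** — per-pixel temporal standard-deviation
  maps; per-compartment bleaching kinetics with exponential rate fits.
* **Statistics** — Tukey boxplot summaries (type-7 quantiles,
  1.5×IQR whiskers), two-sided paired *t* tests, paired pre/post census
  comparisons.
* **Synthetic phantoms** — a ground-truthed generator for dense marrow
  volumes, flowing-RBC vessel networks (constant or stepwise speeds) and
  bleaching series, which the entire test suite runs against.

## Worked example

```r
library(negcontrast)

cfg   <- phantom_config(seed = 42)        # 200 cells, 100x100x20 um^3, dz 0.34 um
scene <- generate_marrow_phantom(cfg)     # dark cells in bright interstitium
seg   <- segment_cells_3d(scene$stack)    # 3D marker-controlled watershed
cell_census(seg$cells, prod(cfg$volume_um))
#> cell_census: 200 cells in 2e+05 um^3 => 200 cells per 100x100x20 um^3 ROI

boxplot_summary(seg$cells$mean_intensity)
#> boxplot_summary (n=200): whiskers [46.08, 52.61], box [48.23, 50.02], median 49.15, 0 outlier(s)
```

All 200 ground-truth cells are recovered; the tight intensity box reflects
the uniform appearance of negative-contrast cells (each cell's mean is the
sum of its pixel intensities over its pixel count). For flow:

```r
sc   <- generate_flow_series(flow_phantom_config(seed = 3))  # 5 vessels, 120 fps, 2 s
net  <- build_vessel_network(sc$stack, min_length_um = 40)
prof <- flow_profile_map(sc$stack, net)
prof$estimates[, c("segment_id", "speed_um_s", "confidence", "censored")]
```

which returns one signed speed per vessel segment (unmeasured segments are
reported as `NA` with low confidence, never as zero).

A thin command-line front-end over these functions ships in
`inst/cli/negcontrast.R` (subcommands `phantom`, `cells`, `distances`,
`motion`, `flow`).

## Documentation

The methods vignette
(`vignettes/negative-contrast-quantification.Rmd`) describes the phantom
model, every tunable parameter with units and defaults, the numerical
choices (tie-breaking, censoring, weighting of the Radon objective), and
the package's known limitations.
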