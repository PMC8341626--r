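---
title: "Quantifying negative-contrast intravital microscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying negative-contrast intravital microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negcontrast)
```

## The imaging problem

In intravital two-photon microscopy of bone marrow or lymph node, routinely
injected vascular and lymphatic tracers (fluorescent dextrans, Evans blue)
leak into and perfuse the interstitial space. The extracellular fluid then
glows while unlabeled cells remain dark: every cell appears in *negative
contrast*, outlined by the dye-filled clefts between cells. This single
fluorescence channel therefore carries a complete map of the cellular
landscape — cell positions, sizes, packing density, motion, and the dark
silhouettes of red blood cells flowing through vessels — without any
cell-directed label.

`negcontrast` implements the quantification chain for such data:

1. **Preprocessing** — LUT inversion (`invert_lut`), percentile contrast
   enhancement (`enhance_contrast`), background estimation
   (`estimate_background`), vessel-signal removal
   (`remove_vessel_signal`) and exclusion masks
   (`build_exclusion_mask`).
2. **Cell detection** — marker-controlled watershed on the dark-cell
   polarity, in 2D per section (`detect_cells_2d`) with a sphere-packing
   model linking sections into 3D records (`build_3d_packing`), or
   directly in 3D (`segment_cells_3d`); censuses of density and diameter
   (`cell_census`, `cell_density`, `diameter_fraction_below`).
3. **Spatial statistics** — anisotropic Euclidean distance from cell
   centroids to the nearest vessel wall (`distance_to_vessel`) and a
   uniform random-dot reference (`random_dot_reference`).
4. **Dynamics** — temporal standard-deviation motion maps
   (`std_dev_map`), digital line scanning (`digital_line_scan`),
   Radon-transform stripe velocimetry (`radon_slope`,
   `speed_from_slope`), rolling velocity time courses
   (`rolling_velocity_series`) and whole-network flow profiles
   (`flow_profile_map`).
5. **Reporting** — Tukey boxplot summaries (`boxplot_summary`), paired
   *t* comparisons of matched censuses (`paired_t_test`,
   `census_comparison`).

Because in vivo stacks of this kind are not generally available, the
package ships a first-class synthetic phantom generator with complete
ground truth; every stage of the pipeline is validated against it.

## The phantom: what it emulates and what it does not

`generate_marrow_phantom()` renders dark, roughly spherical cells (8-bit
level 40 by default) in a bright interstitium (level 200), over a
100 × 100 × 20 µm³ volume sampled at 0.5 × 0.5 × 0.34 µm voxels — the
z-step of a typical high-resolution two-photon stack. Cell radii follow a
truncated normal N(5, 1) µm with a 3 µm floor. Gaussian noise with
standard deviation 5 % of the interstitium level (optionally preceded by
Poisson resampling) emulates two-photon shot noise; no published SNR value
exists for this regime, so the level is a package choice.

Three design decisions deserve explanation:

* **Overlap tolerance 0.35.** Marrow is tightly packed: 200 cells of mean
  radius 5 µm occupy roughly 59 % of the standard ROI volume, beyond the
  jamming limit (~38 %) of hard-sphere rejection sampling. Real marrow
  cells are deformable and press against each other, so the generator
  treats the nominal radii as soft: centers may approach to
  `(r_i + r_j) × (1 − 0.35)`. The tolerance was calibrated once, purely
  so that the placement sampler succeeds robustly at the target density,
  and is configurable down to 0 for sparse, strictly non-overlapping
  scenes.
* **The interstitial film.** Where two soft spheres interpenetrate,
  voxels are assigned to the nearest cell surface and a thin bright film
  (default 0.8 µm) is preserved along the contact surface. This mirrors
  the physical situation: the dye-filled cleft between packed cells is
  often below the optical resolution but still detectable, and it is
  precisely what makes watershed separation of touching cells possible in
  real data. Sphere boundaries are anti-aliased over a 0.5 µm ramp.
* **z clipping.** Cells are wholly inside the volume laterally but may
  be clipped by the top and bottom faces (placement margin r/2), exactly
  as an optical section crops cells at its boundaries.

`generate_flow_series()` renders a 2D vascular network at video rate:
bright plasma-filled tubes (level 220) on a dimmer tissue background
(level 100), with trains of dark discs (RBC-sized, radius 2.5 µm)
advancing along each path by `v·Δt` per frame with sub-voxel anti-aliased
stamping. Disc gaps are drawn uniformly within ±30 % of the nominal
spacing: a perfectly regular train would alias stroboscopically whenever
`v·Δt` is commensurate with the spacing, a degeneracy real blood does not
have. Speeds may be constant or stepwise profiles; positive speed runs
along the stored path orientation, and the per-frame speed matrix is
recorded as ground truth.

`generate_bleaching_series()` emulates the photobleaching comparison
between labeled cells and replenished interstitial dye: the cell
compartment is set to a bright label level (a fluorescent-protein
reporter), bleached by `(1 − rate)^frame`, and observed with fresh noise
per frame, while the interstitium stays flat.

The phantoms deliberately do **not** model the optical point-spread
function, depth-dependent aberration or scattering through bone, dye
leakage kinetics, or cell motility between frames of a z-stack. Passing
the phantom suite therefore demonstrates the correctness of the
*algorithms* under realistic geometry and noise, not robustness to every
optical artifact of in vivo data.

## Segmentation model and parameters

Detection operates on the dark-cell polarity (cells darker than the
interstitium); bright-polarity input is handled by an internal flip, so
detection is equivariant to LUT inversion.

* **Smoothing sigma** (`smooth_sigma_um`, default one xy pixel): applied
  anisotropy-aware, i.e. converted to per-axis voxel units, so the
  0.34 µm z-step is not over-smoothed.
* **Foreground threshold** (`threshold`, default Otsu on the smoothed
  image): separates the dark cell population from the bright
  interstitium. Otsu is reliable when both classes are well represented;
  for degenerate scenes (a single small object in a large field) an
  explicit threshold should be passed.
* **Marker depth** (`h_frac`, default 0.1 of the smoothed dynamic
  range): markers are the regional minima of the h-minima transform,
  computed by grayscale reconstruction. Shallow noise minima are filled;
  each cell contributes one marker.
* **Flooding**: Meyer's priority flood over the foreground, 8/26
  connectivity, with queue ties broken by insertion order in lexicographic
  voxel order — the segmentation is bit-reproducible.
* **Size filters** (`min_diameter_um` 3, `max_diameter_um` 25): applied
  to the area (2D) or volume (3D) equivalent of the diameter bounds.
  Cells touching the ROI border are kept (they count for density); sizes
  of border-clipped cells are biased and should be interpreted with the
  diameter histogram's caveats.

The 2D→3D packing model assumes roughly spherical cells: per-slice
regions are linked across z when centroids fall within
`link_radius_um` (default 0.6 × the median 2D equivalent radius) and the
equivalent-radius ratio is at least 0.1; a track becomes one cell with
area-weighted z centroid and diameter `2·sqrt(A_max/π)`. Direct 3D mode
reports `2·(3V/4π)^{1/3}` instead; both conventions are reported because
"cell size" is not operationally unique, with the volume-derived value
preferred in 3D mode.

## Distances

`distance_to_vessel` computes the exact anisotropic Euclidean distance
transform (separable parabolic envelopes) of the vessel mask and samples
it at centroid positions by trilinear interpolation; positions whose
containing voxel lies in the mask report 0. The "vessel wall" is the
binary mask surface (distance to the nearest blood-vessel wall), not the
centerline. Physical coordinates
follow the voxel-center convention `coord = (index − 0.5) × voxel_size`
throughout the package. On volumes up to 50³ the transform is verified in
the test suite against exhaustive nearest-vessel-voxel search to within
one voxel diagonal.

## Velocimetry model

A kymograph is the digital line scan of a straight vessel segment: rows
are frames (time increasing downward), columns are arc positions at
`Δs = min(dx, dy)`, each sample bilinearly interpolated and averaged over
`line_width_px = 3` perpendicular offsets. A stationary dark cell traces
a vertical stripe; motion tilts the stripe, and
`speed = tan(angle) × Δs/Δt`, signed along the stored segment
orientation.

The stripe angle is found by maximizing, over a 0.25° grid spanning
(−89.75°, 89.75°), the count-weighted variance of the Radon projection
profile of the mean-subtracted kymograph. Two numerical details matter:

* Bins with fewer than half the maximal pixel count (the corners of the
  rotated support) are discarded, and the remaining per-bin means are
  weighted by their counts. Unweighted means would let sparsely filled
  bins inflate the objective at off-stripe angles.
* Exact ties break toward the smaller absolute angle, so featureless or
  symmetric kymographs resolve deterministically.

The peak sharpness — (maximum − median) of the objective in units of its
interquartile range — is reported as a confidence; segments below
`confidence_min = 3` are reported as *unmeasured*, never as zero. Speeds
beyond the reportable bound
`v_max = segment_length × frame_rate / min_rows` (the fastest stripe
still crossing ≥ `min_rows = 3` rows) are censored at `v_max`, not
extrapolated.

Vessel segments come from a global Otsu threshold of the temporally
averaged series, slice-wise morphological closing (radius 3 px, bridging
occlusions up to about one flowing-cell radius), hole filling, Zhang–Suen
thinning, and a line Hough transform (1° × 1 px bins) with greedy peak
acceptance, suppression of candidates overlapping an accepted line's
support by more than 0.5, and ties broken by (angle, offset). The
accepted segment geometry is the straight line between the extreme
projections of its supporting skeleton pixels: using the raw pixel chain
would inflate the arc length of slanted segments by up to ~8 % and bias
all speeds upward by the same factor. Curved vessels are covered by
chains of straight segments, matching the straight-segment line-scan
convention; the Hough step runs globally with suppression rather than per
connected component.

For rolling velocity at 30 fps the package default follows the
one-estimate-per-0.1 s convention (step 3 rows); the window is the
caller's choice, with 0.5 s used in the validation suite — short windows
(< ~10 rows) cannot discriminate fast, dense stripe patterns reliably.

## Statistics

Quartiles use linear interpolation between order statistics
(`stats::quantile` type 7, the common plotting default), making boxplot
summaries bit-reproducible; whiskers are Tukey-style at 1.5 × IQR.
Paired comparisons use the classical two-sided paired *t* test on
`post − pre` differences, with zero-variance differences reported as an
exact-equality signal. Matched-ROI censuses are compared per ROI (the
pairing unit); aggregation per subject first, when subjects contribute
several ROIs, is left to the caller.

## Validation scales

The test suite and `scripts/acceptance.R` run entirely on phantoms at
the following problem sizes, chosen to exercise the study conditions
while remaining single-CPU friendly: 200-cell marrow volumes
(100 × 100 × 20 µm³, 200 × 200 × 59 voxels) for segmentation recovery;
50³-voxel volumes for distance-oracle equivalence; a five-vessel
256 × 128 µm network at 120 fps for 2 s for flow recovery; a 3 s, 30 fps
series for change-point detection; 100 seeded placement replicates (3
matched ROIs each) plus one fully rendered pre/post pair for the census
comparison; and 50-frame bleaching series. Statistical replicates of the
census comparison are built from the generator's placement stage
(`sample_cell_packing`), which is exactly the placement the renderer
consumes.

## A worked example

```{r example, eval = FALSE}
cfg <- phantom_config(seed = 42)           # 200 cells, 100x100x20 um^3
scene <- generate_marrow_phantom(cfg)
seg <- segment_cells_3d(scene$stack)
census <- cell_census(seg$cells, prod(cfg$volume_um))
census
```

Run non-interactively this prints the detected count and the density per
standard ROI; the acceptance script (`scripts/acceptance.R`) recomputes
these together with the distance, flow, rolling-velocity, census and
bleaching quantities and writes them as JSON.

## Known limitations

* Skeletonization and Hough segment selection are 2D (per-plane); 3D
  networks are handled by repeating the analysis at each imaging depth.
* The sphere-packing model can merge deeply interpenetrating cells whose
  shared film is thinner than a voxel, and single-slice debris is only
  kept above an area floor; both effects are bounded by the
  5 % count-error check in the test suite.
* Otsu thresholds assume both intensity classes are represented; pass an
  explicit threshold for near-degenerate scenes.
* Speeds are in-plane; through-plane flow components are invisible to a
  2D line scan.
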