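---
title: "Classifying replication nanostructures in dual-channel 3D stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying replication nanostructures in dual-channel 3D stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spark3d)
```

## The measurement problem

Sequential dual-pulse labelling of nascent DNA (a clickable thymidine
analogue first, a fluorescent dUTP second) turns replication kinetics into
geometry: a fork that ran through both pulses leaves one focus per channel,
slightly offset; an origin that fired bidirectionally inside the pulse
window leaves one first-pulse focus flanked by two second-pulse foci; two
converging forks leave the mirror image. In early-S nuclei these
nanostructures are dense (hundreds per nucleus) but mostly resolvable at
super-resolution. `spark3d` turns two-channel 3D stacks plus a 2D nuclear
mask into per-event and per-nucleus kinetics statistics, and ships a
simulator that makes every stage testable against planted ground truth.

## The analysis chain and its assumptions

1. **Anisotropy correction.** Microscope stacks have a z step several times
   the lateral pixel; all later geometry assumes isotropic voxels, so the z
   axis is resampled by `f = z_spacing / xy_spacing` with linear
   interpolation (`correct_anisotropy()`). The same formula handles `f < 1`.
   Output length is `round(nz * f)`; already-isotropic stacks pass through
   untouched. Assumption: intensity varies smoothly at the z-step scale,
   which holds for diffraction-shaped foci.
2. **Voronoi-Otsu segmentation** (`voronoi_otsu_segment()`): Gaussian blur
   at `blur_sigma`; spot detection as 26-neighbourhood local maxima of the
   volume blurred at `spot_sigma` (plateau maxima are merged into one seed);
   a single global Otsu threshold on the blurred volume; seeded
   watershedding of the thresholded region from the seeds, splitting
   touching foci along the ridge between their maxima. Assumption: one
   intensity threshold per nucleus volume is adequate — foci are far
   brighter than background and shading has been handled upstream.
3. **Curation.** Foci whose centroid falls outside the 2D nuclear mask are
   discarded (`apply_nuclear_mask()`), then foci with fewer than
   `min_voxels = 50` voxels (strict less-than: a 50-voxel focus survives)
   are removed (`filter_small()`).
4. **Overlap graph and classification.** Exact shared-voxel counts between
   the two channels' labels form a bipartite graph. Each overlap is scored
   relative to the largest overlap of each participating focus; only
   overlaps strictly above `overlap_rel_threshold = 0.20` of that maximum
   survive, which prioritises the dominant partner in crowded
   neighbourhoods. Connected components of the pruned graph classify by
   composition: (1,0)/(0,1) single-colour, (1,1) ongoing, (1,2) star
   initiation, (2,1) star termination, everything else — including any
   component of more than `max_foci_per_event = 3` foci — crowded.
   Exclusivity ("two flanks that overlap only this centre focus") is
   automatic on connected components of the kept-edge graph, because a
   flank with another kept partner would pull that partner into the same
   component.
5. **Geometry.** Centroid distance (ongoing), intersection-over-union
   volume-overlap ratio (all dual events), inter-fork angle via the clamped
   arccosine (initiation/termination), event volume as union voxels times
   voxel volume; nearest-neighbour distances within and across channels;
   2D distance-transform depth to the nuclear periphery; per-nucleus
   summaries; Mann-Whitney U comparisons with a Bonferroni cap.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_voxels` | 50 | voxels | removes out-of-focus or shot-noise fragments; strict `<` |
| `overlap_rel_threshold` | 0.20 | fraction of per-focus max overlap | keeps only dominant inter-channel contacts; strict `>` |
| `max_foci_per_event` | 3 | foci | larger components are concatenated/crowded structures |
| `blur_sigma`, `spot_sigma` | 1 isotropic voxel | µm | the workflow's conventional scales; the source pipelines do not publish values, so both are config-exposed |
| `fibre_rate_kbp_per_um` | 2.59 | kbp/µm | standard stretched-fibre extension rate for track-length conversion |

## The simulator: what it emulates, what it does not

`simulate_nucleus()` plants events inside an elliptical 2D nucleus
footprint and a z slab, renders every blob as an isotropic 3D Gaussian
sampled on the anisotropic grid (so anisotropy correction is genuinely
exercised), and corrupts the signal with Poisson photon noise plus Gaussian
read noise, rounded to integer camera counts. Placement is bounded
rejection sampling: blobs of different events keep at least
`min_event_gap` between them, and exceeding `10 * n_events` attempts is an
explicit placement-failure error, never silent truncation.

Defaults encode the study conditions the validation suite runs at: a
448 × 448 × 32 grid at 50 nm lateral / 125 nm axial spacing, 500 events
mixed 0.1/0.8/0.1 over initiation/ongoing/termination, foci of 125 nm SD,
centre-to-flank separation 0.30 ± 0.05 µm, inter-flank angles uniform on
90-180°, amplitude 200 photons over a 20-photon background (peak SNR ≈ 13)
and a 0.75 µm (6 SD) inter-event gap. The focus SD is chosen so a rendered
focus comfortably exceeds the 50-voxel cutoff at the default spacing —
absolute focus sizes in voxels are not published for real data, so this is
a package choice, not a fit. The angle floor of 90° keeps the two flanks of
an initiation resolvable at the default separation; real initiations with
acute inter-fork angles would partially merge and land in the crowded or
ongoing classes, which is a genuine limitation of intensity-based
segmentation, not of the simulator.

Crowded events are planted as four mutually overlapping blobs (two per
channel on orthogonal axes), matching the "more than 3 foci" exclusion
rule while keeping same-channel blobs separable.

The simulator does **not** model the optical transfer function or
structured-illumination reconstruction artefacts (stripes, halos), chromatic
shift, spherical aberration, photobleaching, or density-dependent focus
clustering of mid/late-S nuclei. Passing recovery tests therefore show the
chain is correct on well-formed, resolvable input at realistic noise — they
do not certify performance on reconstruction artefacts or concatenated
late-S foci, which real analyses must curate by selecting early-S nuclei.

## Numerical choices

* **Axis order and units.** Arrays are (z, y, x), voxel indices 0-based in
  physical conversions (voxel centre at `index * spacing`), all outputs in
  micrometres. One convention everywhere removes silent ambiguity.
* **Otsu.** 256-bin histogram over the data range, maximising between-class
  variance; a constant volume yields zero labels rather than an error.
* **Maxima ties.** Plateau maxima (equal neighbouring values) are merged
  into a single seed by 26-connected labelling, so a blob whose apex falls
  between voxels still yields exactly one focus.
* **Watershed ties.** The priority flood breaks equal-intensity ties
  first-in-first-out, making label assignment deterministic.
* **Overlap-rule join.** The >20% rule is evaluated from each focus's own
  perspective; a record is kept only when it passes for *both* endpoints.
  The symmetric (AND) join is order-independent and makes channel-swap
  antisymmetry (initiation ↔ termination) exact on any input; the
  asymmetric OR variant is available via `overlap_rule = "or"`. Ties for
  the per-focus maximum all score 1 and are kept.
* **Nucleus assignment** is by focus centroid, not any-voxel overlap:
  deterministic for foci straddling the mask edge.
* **Event volume** and the overlap ratio's denominator use the *union* of
  member-foci voxels, avoiding double-counting the intersection.
* **Angles** clamp the cosine to [-1, 1] before `acos`; coincident
  centroids are an error rather than NaN.
* **Periphery distance** is 2D (distance transform of the max-projection
  mask), because nuclear masks are 2D by construction; a 3D distance would
  pretend to axial information the masks do not carry.
* **Mann-Whitney U** uses the exact distribution when both groups have at
  most 8 untied values, otherwise the normal approximation with tie
  correction; Bonferroni is the capped product `min(1, p * n_tests)`.
* **Percentiles** (QIBC p95 - p5) use the linear-interpolation convention
  (R type 7); conventions differ enough across software that this is
  documented behaviour.
* **Illumination correction** fits a 2nd-order polynomial surface (the
  usual fit-polynomial convention) and divides, preserving the mean;
  per-tile adaptive Otsu thresholds are clamped to 0.7-1.5 of the global
  threshold so empty tiles cannot hallucinate foreground.
* **TIFF storage** quantises intensities to 16-bit integers (the native
  camera range); simulated integer photon counts round-trip exactly, and
  voxel spacing always travels in an explicit JSON sidecar — missing
  spacing is an error, never a silent default.

## Validation problem sizes

The test suite validates each stage against independent oracles (analytic
geometry, brute-force voxel counting, union-find, permutation enumeration,
closed-form distributions) at small sizes, plus end-to-end recovery on
simulated nuclei: 40-event scenes for per-file checks and one 500-event
scene at the default conditions for the headline recovery test
(≥ 95% type accuracy, centroid-distance MAE within one voxel pitch, angle
MAE below 5°, planted mixture inside 99% binomial confidence intervals).
`scripts/acceptance.R` re-runs that recovery from scratch at a
caller-supplied seed.

## Known limitations

* Intensity-based segmentation cannot split foci closer than roughly twice
  the blur scale; very short separations bias ongoing events toward high
  overlap ratios, and acute initiations toward misclassification.
* A single global Otsu threshold per volume assumes one nucleus per field
  or comparable brightness across nuclei; per-nucleus local thresholds
  could be layered on top.
* The retention fraction depends strongly on scene density; the simulator's
  well-separated defaults give near-total retention, unlike crowded real
  nuclei where roughly half of detected foci survive curation.
* No time-lapse tracking, no probabilistic event assignment, no spatial
  point-process statistics beyond nearest-neighbour and periphery
  distances.
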