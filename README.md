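# spark3d

Quantifying DNA replication kinetics from dual-pulse nascent-DNA labelling
imaged in 3D. `spark3d` is for cell biologists who label replicating DNA with
two sequential nucleotide pulses (a clickable thymidine analogue such as EdU,
then a fluorescent dUTP), image nuclei as two-channel 3D super-resolution
stacks, and want per-nucleus replication statistics out of the other end:
how many forks are running, where origins fired bidirectionally, where forks
converged, how far forks travelled between the pulses, and how events sit
within the nucleus.

## What it computes

Each channel volume is made isotropic (linear z resampling by
`f = z_spacing / xy_spacing`) and segmented with a **Voronoi-Otsu labelling
workflow**: Gaussian blur, spot detection by 3D local maxima, global Otsu
thresholding, and seeded watershedding of the thresholded region. Foci
outside the 2D nuclear mask or smaller than 50 voxels are discarded.

Foci of the two channels are then joined into a bipartite overlap graph.
For each focus, overlaps are scored relative to its largest overlap and only
overlaps exceeding 20% of that maximum (for both participating foci) are
kept. Connected components classify as:

| component (EdU, dUTP) | type | biology |
|---|---|---|
| (1, 0) or (0, 1) | single-colour | synthesis during one pulse only |
| (1, 1) | ongoing | one fork running through both pulses |
| (1, 2) star | initiation | bidirectional firing in the pulse window |
| (2, 1) star | termination | two forks converging |
| anything else (> 3 foci) | crowded | excluded from kinetics inference |

Per event, the package measures the EdU-dUTP **centroid distance** (ongoing
events; in micrometres, shrinks when forks stall), the **volume-overlap
ratio** (intersection over union of member foci; grows when forks stall),
and the **inter-fork angle** of initiations/terminations
(`acos(v1 . v2 / |v1||v2|)` between the centre-to-flank centroid vectors).
Per nucleus it reports event counts, relative frequencies among the dual
types, the retained-focus fraction, nearest-neighbour and
nuclear-periphery distance distributions, and Mann-Whitney U group
comparisons with Bonferroni correction.

A first-class **simulator** (`simulate_nucleus()`) plants ground-truth
events (Gaussian foci, Poisson photon noise, Gaussian read noise, anisotropic
voxels) inside an elliptical nucleus so the entire chain is verifiable
without microscopy data, and a **QIBC module** handles widefield
cytometry: polynomial illumination correction, adaptive-Otsu nucleus
detection with a 6-40 px diameter gate, integrated intensities,
fixed-threshold S-phase gating and p95-p5 dose-time matrices.

## Worked example

```r
library(spark3d)

sim <- simulate_nucleus(sim_config(n_events = 40, seed = 7,
                                   grid_shape = c(20L, 192L, 192L),
                                   nucleus_semiaxes = c(y = 4.2, x = 4.2, z = 0.8)))
run <- run_spark(sim$stack, sim$mask)
run
#> <spark_run> 89 foci, 40 events (initiation: 7, ongoing: 31, termination: 2)

matched <- match_events(sim$truth, run)
mean(matched$detected_type == matched$true_type)
#> [1] 1

ong <- subset(matched, true_type == "ongoing")
mean(abs(ong$centroid_distance_um - ong$true_separation))
#> [1] 0.002034612
```

All 40 planted events are recovered with their planted types, and the
measured EdU-dUTP centroid distances of ongoing events match the planted
separations to ~2 nm — far below the 50 nm voxel pitch, because centroids of
segmented foci average over hundreds of voxels. The two scalar utilities
reproduce the field's standard conversions:

```r
tract_to_kb(6, rate_kbp_per_um = 2.59)   # 6 um fibre tract
#> [1] 15.54                              # ~16 kb of nascent DNA
fold_efficiency(15, 10, 240, 100)        # 15 min/10 uM vs 240 min/100 uM
#> [1] 160
```

A command-line interface is installed as `exec/spark3d` with subcommands
`simulate`, `analyze`, `benchmark` and `qibc`; see `?cli_main`.

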