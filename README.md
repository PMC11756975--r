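# quadratvol

Vegetation volume and biomass allometry from photo-quadrat point clouds.

## What this is for

Rangeland monitoring crews photograph small quadrat sampling frames
(0.4 m x 0.5 m, 0.2 m^2) and reconstruct dense 3-D point clouds of the
vegetation by Structure-from-Motion. In invasive annual-grass systems
(medusahead, cheatgrass) the plots carry a thick mat of dead litter that
hides the mineral soil, so separating "ground" from "biomass" in the cloud
is the hard step before any volume can be measured. `quadratvol` implements
the full per-plot and cohort workflow for this setting:

- **Denoising** — k-nearest-neighbour statistical outlier removal
  (threshold `mu + m*sigma` of the mean k-NN distances, `k = 10`, `m = 1`).
- **Ground classification** — the simple morphological filter (SMRF:
  minimum-elevation raster, progressive disk openings of radius 1..10
  cells, elevation threshold 0.11 m, slope threshold 0.1, elevation scale
  0.9), followed by iterative two-component Gaussian-mixture refinement of
  the ground class, merging the high component into vegetation until the
  vegetation voxel volume stops improving by more than 5%.
- **Terrain surface** — triangulated linear interpolation of the ground
  class on a 0.01 m grid (exact on planes), nearest-neighbour extrapolated.
- **Three volume estimators** — canopy height model (per-cell maximum
  height, 7x7 inverse-distance gap fill, mean height x 0.2 m^2), 3-D convex
  hull, and voxel occupancy at edge lengths from 2 to 100 mm.
- **Allometry and screening** — ordinary and log-log regressions
  `B = a + b V` and `ln B = a + b ln V` per estimator and biomass component,
  with Cohen's `f^2 = R^2/(1-R^2)` and noncentral-F achieved power
  (significance requires power >= 0.90); paired Wilcoxon signed-rank
  comparisons across voxel sizes (exact null for n <= 25, Holm-corrected);
  total-least-squares line and Lin's concordance correlation coefficient
  `CCC = 2 s_xy / (s_x^2 + s_y^2 + (x̄ - ȳ)^2)` for method agreement.
- **A synthetic scene generator** — terrain, litter mat, curved stems, with
  occlusion and sensor noise, exact per-point labels, analytic reference
  ground surfaces and reference volumes, so the entire pipeline is testable
  end to end without field data.

## Worked example

```r
library(quadratvol)

scene <- generate_scene(scene_params(seed = 42))   # litter + stems + terrain
cloud <- sample_cloud(scene)                       # labelled SfM-like cloud
cloud
#> <point_cloud: 416926 points, labels (90936 ground, 325990 vegetation)>

labels <- smrf_classify(cloud, frame = quadrat_frame())
cls <- iterative_refine(cloud, labels, seed = 42)
cls$vegetation_volume_trace
#> 0.004019 0.005415 0.007602      # m^3, non-decreasing across merges
```

The trace shows the refinement at work: SMRF alone finds the tall stems
(0.0040 m^3 of vegetation voxels at 5 mm) but leaves the litter mat in the
ground class; two committed mixture passes move it across, nearly doubling
the recovered vegetation volume.

```r
cloud$labels <- cls$labels
terrain <- fit_ground_surface(subset_cloud(cloud, cls$labels == 1), quadrat_frame())
above <- points_above_surface(cloud, terrain)
chm <- compute_chm(above$heights, above$cloud$coords[, 1:2], quadrat_frame())
c(chm$mean_height, chm$volume)
#> 0.229 0.0459                    # mean canopy height (m), CHM volume (m^3)

veg <- subset_cloud(cloud, cls$labels == 2)
voxel_size_sweep(veg, c(0.002, 0.005, 0.01, 0.05, 0.1),
                 origin = c(0, 0, min(terrain$z)))
#>   edge_m occupied_count   volume_m3
#> 1  0.002         234951 0.001879608
#> 2  0.005          60781 0.007597625
#> 3  0.010          18606 0.018606000
#> 4  0.050            757 0.094625000
#> 5  0.100            119 0.119000000
```

Voxel volume grows with edge length (coarser voxels bound more empty space);
the 5 mm edge (0.125 cm^3 voxels) is the working scale for fine grasses.
Because the generator knows every point's true class, the classification can
be scored exactly — this scene recovers ground recall 0.987 and vegetation
IoU 0.987.

Cohort-level fitting, for a directory of plots plus a biomass CSV
(`plot_id,annual_g,perennial_g,forb_g,litter_g`):

```r
synthesize_cohort("plots/", n_plots = 10, seed = 7)   # or your own data
res <- run_cohort("plots/", "plots/biomass.csv", pipeline_config(),
                  out_dir = "results/")
head(res$report)    # estimator x component x {linear, log} with f^2 power
res$agreement       # reconstructed- vs reference-surface volume agreement
```

A command-line front end with the same verbs (`synthesize`, `classify`,
`volumes`, `allometry`, `agreement`, `run`) is installed at
`inst/exec/quadratvol`.

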