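---
title: "Vegetation volumetrics from photo-quadrat point clouds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vegetation volumetrics from photo-quadrat point clouds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadratvol)
```

## The problem

Destructive biomass harvests on rangeland quadrats are slow and cannot be
repeated on the same plot. Close-range photography around a small sampling
frame (here 0.4 m x 0.5 m, 0.2 m^2), reconstructed into a dense 3-D point
cloud by Structure-from-Motion (SfM), offers a non-destructive proxy: if the
volume occupied by vegetation can be measured from the cloud, an allometric
model can convert volume to dry-weight biomass. The hard part in invasive
annual-grass systems (medusahead, cheatgrass) is that a mat of dead litter
covers most of the mineral soil, so the "ground" the cloud shows is often the
top of the litter — which is itself biomass.

`quadratvol` implements the full chain from raw per-plot clouds to cohort
statistics, plus a parametric scene generator that produces labelled clouds
with exact reference surfaces so every stage can be validated without field
data.

## Per-plot workflow

1. **Clip** to the quadrat frame. The frame is a half-open rectangle
   `[x0, x0+0.4) x [y0, y0+0.5)`; half-open intervals are used for the frame
   and for every later gridding step so no point is ever counted twice across
   a shared boundary.
2. **Denoise** with the classic k-nearest-neighbour statistical outlier
   filter: a point is dropped when its mean distance to its `k = 10`
   neighbours exceeds `mu + m * sigma` over the cloud (`m = 1` by default).
   An absolute-distance mode is available because the filter is sometimes
   quoted with a fixed threshold; the sigma rule is the cited algorithm's
   definition and is the default. One pass only.
3. **SMRF classification.** A minimum-elevation raster (0.01 m cells) is
   opened progressively with disk windows of radius 1..10 cells; a cell that
   drops under the opening at radius `w` by more than
   `0.9 * 0.1 * (w * 0.01) m` is flagged as an object cell. Points within
   0.11 m of the interpolated unflagged minimum surface are ground. The 11 cm
   elevation threshold, 0.1 slope threshold, 0.9 elevation scale and radius
   10 are the field parameterization for these mostly flat plots and are the
   package defaults. Note what the 11 cm tolerance implies: a 3 cm litter mat
   passes the test, so the SMRF ground class still contains most of the
   litter. That is by design — the filter's job is only to remove tall
   vegetation robustly.
4. **Iterative mixture refinement.** The remaining contamination is removed
   by fitting a two-component 1-D Gaussian mixture to a per-point feature of
   the current ground class and merging the high component into vegetation,
   repeatedly, with the vegetation class only ever growing (additive merge).
   A proposed move is kept when (a) the two fitted components are genuinely
   bimodal and (b) the vegetation voxel volume (5 mm voxels) grows by more
   than 5%; otherwise the labels revert and iteration stops. Up to 10 passes
   are allowed; in practice litter-covered scenes stop after 2-3.
5. **Terrain fit.** A triangulated linear interpolation of the ground-class
   points, evaluated at 0.01 m cell centres, nearest-neighbour extrapolated
   outside their convex hull. Linear interpolation over a triangulation
   reproduces planes exactly, which is the natural correctness standard for
   a soil-microtopography model. Above ~50k ground points the input is
   decimated to one per 5 mm cell (the median-elevation point, an actual
   input point, so plane exactness survives decimation).
6. **Volumes.** Three estimators, all on the denoised vegetation class:
   - *Canopy height model*: per-cell maximum height above terrain at 0.01 m,
     empty cells filled by inverse-distance weighting (power 2) within a
     7 x 7 window, cells with no filled neighbour staying empty; the plot
     mean over non-empty cells times the 0.2 m^2 frame area is the volume.
   - *Convex hull*: the exact 3-D hull volume (incremental construction).
   - *Voxel occupancy*: distinct occupied cubic cells times cell volume, at
     edges from 2 to 100 mm, all sharing one origin (the frame corner at the
     terrain minimum) so volumes at nested edges are monotone by
     construction.

## The refinement feature: elevation vs curvature

Both features are implemented; `refine_params(feature = ...)` selects one.

*Curvature* is the surface variation `l3 / (l1 + l2 + l3)` of the
neighbourhood covariance (the point plus its `k` nearest neighbours; 50 on
the first pass, 200 after, each pass running on the previous pass's ground
output). It is bounded (0 for planes, 1/3 for isotropic scatter), fast, and
captures the soil-smooth / litter-rough contrast. Its weakness is
structural: wherever a neighbourhood straddles a litter border or a stem
base, smooth soil inherits a rough neighbourhood, and on synthetic scenes
with known labels roughly a quarter of the soil points sit in that blurred
zone — moving them costs ground recall that no threshold can buy back.

*Elevation* (the default) is the height of each ground-class point above the
per-cell minimum-elevation raster of that same ground class. The minimum
raster is robust to litter dominating the point count: wherever even a few
soil points are visible through the mat, the minimum rides on soil. Soil
then collapses to a sharp mode near zero height while the litter top sits a
mat-thickness higher, the mixture is cleanly bimodal, and on bare soil the
feature is unimodal so the refinement correctly does nothing. On labelled
synthetic scenes this feature reaches ground recall and vegetation IoU near
0.99, against IoU ~0.87 with significant recall loss for curvature — the
same ordering the original field study reported when it concluded that
elevation-based clusters were the better refinement feature.

A single-population guard is needed because a 2-component EM fit *always*
splits something; without it, the tail of a perfectly unimodal feature would
be moved whenever the moved points are spatially diffuse enough to inflate
the voxel-volume criterion. The volume-improvement rule alone is therefore
necessary but not sufficient. The guard is expressed in the feature's own
units. For elevation the component means must differ by at least
`min_gap_m = 4 mm`: on bare soil the EM split of the (unimodal) height
distribution lands a millimeter or two apart — the sensor-noise scale —
while litter sits a mat-thickness (~30 mm) and stem bases ~6-8 mm above the
soil mode, so the 4 mm cut cleanly separates "no second population" from a
real one. (A relative criterion such as Ashman's D cannot make this call:
on labelled scenes the unimodal bare-soil fits reach D ~2.2, inside the
range genuine soil/litter mixtures occupy.) For curvature, which is
dimensionless, Ashman's `D >= 2` is used, and since its genuine mixtures can
land near D = 1.6-2.1, a lower `min_separation` (~1.5) is appropriate when
running in curvature mode. The guards plus the volume rule terminate on bare
terrain with labels untouched.

## Cohort statistics

- **Allometry**: `biomass = a + b * volume` (linear) and
  `ln(biomass) = a + b * ln(volume)` (the power law), per estimator and per
  biomass component (annual, perennial, forb, litter, vegetation total,
  total). R^2 for log fits is reported on the log-log scale; RMSE is always
  back-transformed to grams so the two forms are comparable in one table.
  Natural logarithms throughout (the base only rescales coefficients).
- **Power screening**: Cohen's `f^2 = R^2 / (1 - R^2)`; achieved power from
  the noncentral F distribution (df 1 and n-2, noncentrality `f^2 * n`,
  alpha 0.05); a fit is reported significant when power >= 0.90.
- **Voxel-size comparison**: volumes at different edges are repeated
  measurements of the same plots, so pairs of edges are compared with a
  *paired* Wilcoxon signed-rank test. The exact null (dynamic-programming
  convolution over midranks, so ties are handled exactly) is used for
  n <= 25, the normal approximation with continuity correction above; Holm
  correction across the family (uniformly more powerful than Bonferroni at
  the same family-wise error).
- **Agreement** between volumes above the reconstructed and the reference
  ground surface: mean absolute relative difference, OLS R^2, total least
  squares line (principal eigenvector of the centred covariance — the right
  line when both variables carry error), and Lin's concordance correlation
  coefficient with population (n-denominator) moments.

## The synthetic generator

`generate_scene()` + `sample_cloud()` emulate what the cameras actually see:

- smooth soil microtopography (sum of three low-frequency sinusoids, 2 cm
  peak-to-peak by default);
- a litter mat over 60% of the frame (disks added until the measured cover
  is within 1.5% of target), ~3 cm thick with plateau-shaped patch profiles
  and 4 mm surface roughness at 1-2 cm wavelengths — only its *top* surface
  is sampled, because passive photogrammetry cannot see inside the mat;
- 300 curved stems, radius 1-3 mm and height 5-60 cm, sampled at 15% of the
  nominal density, reflecting how poorly SfM reconstructs fine, gracile,
  wind-moved stems;
- soil points beneath litter or a stem footprint removed with probability
  0.7 (occlusion), isotropic measurement noise of 0.4 mm (the ground-sample
  distance scale of close-range photography over a 0.2 m^2 frame), then
  greedy thinning to the 1 mm minimum spacing.

Every point carries its true class, so classifier recall/IoU are exact, and
the generating terrain is available analytically both as a function and as
the reference 0.01 m grid.

Two consequences of the geometry are worth stating. First, a minimum-spacing
filter saturates a quasi-planar surface near 1e6 points/m^2 no matter how
many points are requested, so at the default request of 2e6/m^2 the realized
density is set by the exclusion geometry (as it is in real SfM clouds after
spacing filters); the density-tracking contract is tested in the unsaturated
regime. Second, at full occlusion the minimum surface under litter *is* the
litter top, and the refinement cannot recover the soil there — the same
failure mode field studies report for dense mats. The default 0.7 leaves
~30% of under-mat soil visible, which is enough for the minimum raster to
ride on soil essentially everywhere.

What the generator does **not** emulate: SfM matching artifacts (ghost
points, doubled surfaces), wind-blurred stems, lighting-dependent dropout,
rocks and dung, multi-species canopy architecture. Passing the synthetic
suite therefore demonstrates the pipeline's internal correctness and its
behaviour under occlusion and litter cover, not field-level accuracy.

## Numerical choices

- Voxel indices use `floor((coord - origin) / edge)` with half-open cells;
  the shared origin makes nested-edge monotonicity exact rather than
  statistical.
- "Above the surface" is a strict inequality (`z > terrain`), excluding
  ground-touching duplicates.
- The mixture EM is deterministic: seeded k-means initialization, at most
  100 iterations, log-likelihood tolerance 1e-6, variance floored at 1e-10
  of the data variance, posterior ties resolved to the low (ground-like)
  component.
- The convex hull uses scale-relative tolerances (1e-12 of the bounding-box
  diagonal); degenerate inputs (fewer than 4 points, collinear, coplanar)
  return volume 0 with a flag rather than an error, because an empty or
  flat vegetation class is a legitimate plot outcome.
- Biomass is simulated as
  `800 g * (V / 0.006 m^3) ^ 1 * exp(N(0, 0.5^2))`, split 60% litter and
  0.8 : 0.15 : 0.05 annual : perennial : forb. The 0.006 m^3 reference is
  the 5 mm voxel volume of a median default scene, so a median plot draws
  near the coefficient; scale and noise match destructively harvested
  cohorts (tens to thousands of grams, mean near 900 g). Cohort fixtures
  additionally vary litter cover (0.2-0.9), mat thickness (1.5-4.5 cm) and
  stem density (0.1-2x) from plot to plot, without which every plot would
  be statistically identical and cohort regressions would have no
  between-plot signal to fit.

## Problem sizes

The validation suite classifies 20 full-size default scenes (~0.4-0.5
million points each after thinning) for the recovery and agreement
properties, and uses 100 replicates of n = 288 plots for the allometric
recovery statistics; smaller scenes (2e5 points/m^2, 60 stems) back the unit
tests. These sizes were chosen so the full suite runs comfortably on a
single CPU while keeping the scenes at the density regime the method is
meant for.

## Limitations

- The allometric coefficients fitted on synthetic cohorts say nothing about
  field transferability; they close the loop on the generator's own model.
- LAZ (compressed LAS) is not read; decompress externally.
- The hull estimator is intentionally crude (it bounds empty space inside
  the canopy); it is retained because it is a standard comparator.
- Rock/clutter handling is untested; rocks would enter the vegetation class
  exactly as the field workflow's discussion anticipates.
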