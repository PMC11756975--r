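## Synthetic quadrat scenes with exact per-point labels.
##
## Emulates what close-range Structure-from-Motion actually sees on a
## litter-dominated rangeland quadrat: smooth mineral-soil microtopography,
## a rough litter mat covering most of the frame whose interior (and much of
## the ground beneath) is invisible to the cameras, and fine curved grass
## stems that SfM under-samples. Every sampled point carries its true class,
## and the generating terrain is available analytically, so classifier
## recall/IoU and surface-fitting error are exactly measurable.

#' Synthetic scene parameters
#'
#' Defaults describe a typical litter-covered sagebrush-steppe quadrat:
#' ~2 cm of soil microrelief, a litter mat over 60% of the frame about 3 cm
#' thick, 300 fine curved stems 5-60 cm tall, clouds of 2 million points per
#' square meter filtered to a 1 mm minimum spacing, and strong (70%)
#' occlusion of the soil beneath litter.
#'
#' @param seed integer; every draw in the scene derives from it.
#' @param terrain_relief_m peak-to-peak soil relief (m), default 0.02.
#' @param litter_cover_fraction target fraction of frame area under litter.
#' @param litter_thickness_m litter mat thickness (m), default 0.03.
#' @param stem_count number of grass stems, default 300.
#' @param stem_height_range_m stem height range (m), default c(0.05, 0.6).
#' @param point_density_per_m2 nominal surface sampling density, default 2e6.
#' @param min_spacing_m minimum point spacing after thinning (m).
#' @param occlusion_strength probability that a soil point under litter or
#'   canopy is lost to occlusion, in `[0, 1]`.
#' @param noise_sd_m SfM measurement noise, standard deviation per
#'   coordinate (m); default 0.0004, the ground-sample-distance scale of
#'   close-range photography over a 0.2 m^2 frame.
#' @param stem_density_fraction fraction of nominal density realized on stem
#'   surfaces (SfM under-reconstructs fine gracile stems), default 0.15.
#' @param litter_roughness_m amplitude of the litter mat's surface
#'   roughness (m), default 0.004 at ~2 cm wavelength.
#' @param frame the [quadrat_frame()] the scene covers.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(seed = 1L,
                         terrain_relief_m = 0.02,
                         litter_cover_fraction = 0.6,
                         litter_thickness_m = 0.03,
                         stem_count = 300L,
                         stem_height_range_m = c(0.05, 0.6),
                         point_density_per_m2 = 2e6,
                         min_spacing_m = 0.001,
                         occlusion_strength = 0.7,
                         noise_sd_m = 0.0004,
                         stem_density_fraction = 0.15,
                         litter_roughness_m = 0.004,
                         frame = quadrat_frame()) {
  stopifnot(terrain_relief_m >= 0, litter_cover_fraction >= 0,
            litter_cover_fraction <= 1, litter_thickness_m > 0,
            stem_count >= 0, length(stem_height_range_m) == 2L,
            all(stem_height_range_m > 0), point_density_per_m2 > 0,
            min_spacing_m >= 0, occlusion_strength >= 0,
            occlusion_strength <= 1, noise_sd_m >= 0,
            stem_density_fraction > 0, stem_density_fraction <= 1)
  structure(as.list(environment()), class = "scene_params")
}

# smooth low-frequency terrain: three sinusoidal components
.terrain_fun <- function(coefs) {
  force(coefs)
  function(x, y) {
    z <- rep(0, length(x))
    for (i in seq_len(nrow(coefs)))
      z <- z + coefs$amp[i] *
        sin(2 * pi * (coefs$fx[i] * x + coefs$fy[i] * y) + coefs$phase[i])
    z
  }
}

.litter_membership <- function(patches, x, y) {
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(patches)))
    inside <- inside | ((x - patches$cx[i])^2 + (y - patches$cy[i])^2 <
                          patches$r[i]^2)
  inside
}

# plateau-shaped thickness factor in [0, 1]; 0 outside every patch
.litter_thickness_factor <- function(patches, x, y) {
  f <- rep(0, length(x))
  for (i in seq_len(nrow(patches))) {
    d2 <- ((x - patches$cx[i])^2 + (y - patches$cy[i])^2) / patches$r[i]^2
    f <- pmax(f, ifelse(d2 < 1, 1 - d2^2, 0))
  }
  f
}

#' Generate a synthetic quadrat scene
#'
#' Deterministic in `params$seed`. Litter disks are added until the measured
#' covered area fraction (on a 2 mm indicator grid) is within 1.5% of the
#' target, shrinking candidate radii as the target nears. Stems are rooted on
#' the terrain with random lean and quadratic bend.
#'
#' @param params a [scene_params()] set.
#' @return an object of class `synthetic_scene` with the terrain function
#'   and coefficients, litter patches and surface functions, stem table,
#'   and `reference_ground` (the exact terrain on the 0.01 m grid, as a
#'   `terrain_grid`).
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  fr <- params$frame
  scene <- .with_seed(params$seed, {
    coefs <- data.frame(
      amp = params$terrain_relief_m / 2 * c(0.6, 0.3, 0.1),
      fx = runif(3, -1, 1) * c(2, 4, 7),
      fy = runif(3, -1, 1) * c(2, 4, 7),
      phase = runif(3, 0, 2 * pi))
    terrain <- .terrain_fun(coefs)

    # indicator grid for exact-enough coverage measurement
    gx <- seq(fr$x0 + 0.001, fr$x0 + fr$width_x - 0.001, by = 0.002)
    gy <- seq(fr$y0 + 0.001, fr$y0 + fr$width_y - 0.001, by = 0.002)
    G <- cbind(rep(gx, length(gy)), rep(gy, each = length(gx)))
    covered <- rep(FALSE, nrow(G))
    patches <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0))
    target <- params$litter_cover_fraction
    if (target > 0) {
      for (i in seq_len(400L)) {
        cov_now <- mean(covered)
        if (cov_now >= target - 0.015) break
        r <- runif(1, 0.025, 0.07)
        deficit <- target - cov_now
        rmax <- sqrt(deficit * fr$area / pi) * 1.3
        r <- min(r, max(rmax, 0.01))
        cx <- runif(1, fr$x0, fr$x0 + fr$width_x)
        cy <- runif(1, fr$y0, fr$y0 + fr$width_y)
        hit <- (G[, 1] - cx)^2 + (G[, 2] - cy)^2 < r^2
        if (mean(covered | hit) > target + 0.015) next
        covered <- covered | hit
        patches <- rbind(patches, data.frame(cx = cx, cy = cy, r = r))
      }
    }

    rough_phase <- runif(4, 0, 2 * pi)
    n_stem <- params$stem_count
    stems <- if (n_stem > 0) {
      h <- runif(n_stem, params$stem_height_range_m[1], params$stem_height_range_m[2])
      bx <- runif(n_stem, fr$x0, fr$x0 + fr$width_x)
      by <- runif(n_stem, fr$y0, fr$y0 + fr$width_y)
      lean <- runif(n_stem, 0, 25) * pi / 180
      azim <- runif(n_stem, 0, 2 * pi)
      data.frame(
        bx = bx, by = by, bz = terrain(bx, by),
        height = h,
        radius = runif(n_stem, 0.001, 0.003),
        dx = sin(lean) * cos(azim), dy = sin(lean) * sin(azim), dz = cos(lean),
        bend = runif(n_stem, 0, 0.08) * h,
        bend_azim = runif(n_stem, 0, 2 * pi))
    } else {
      data.frame(bx = numeric(0), by = numeric(0), bz = numeric(0),
                 height = numeric(0), radius = numeric(0), dx = numeric(0),
                 dy = numeric(0), dz = numeric(0), bend = numeric(0),
                 bend_azim = numeric(0))
    }
    list(coefs = coefs, patches = patches, rough_phase = rough_phase,
         stems = stems, covered_fraction = mean(covered))
  })

  terrain <- .terrain_fun(scene$coefs)
  rough <- function(x, y) {
    p <- scene$rough_phase
    params$litter_roughness_m *
      (0.6 * sin(2 * pi * x / 0.021 + p[1]) * sin(2 * pi * y / 0.019 + p[2]) +
       0.4 * sin(2 * pi * x / 0.011 + p[3]) * sin(2 * pi * y / 0.013 + p[4]))
  }
  litter_top <- function(x, y) {
    f <- .litter_thickness_factor(scene$patches, x, y)
    terrain(x, y) + params$litter_thickness_m * f + rough(x, y) * (f > 0)
  }

  nx <- max(1L, round(fr$width_x / 0.01))
  ny <- max(1L, round(fr$width_y / 0.01))
  cx <- fr$x0 + (seq_len(nx) - 0.5) * 0.01
  cy <- fr$y0 + (seq_len(ny) - 0.5) * 0.01
  ref <- structure(list(x0 = fr$x0, y0 = fr$y0, cell_size = 0.01,
                        z = matrix(terrain(rep(cx, ny), rep(cy, each = nx)),
                                   nx, ny)),
                   class = "terrain_grid")

  structure(list(params = params, terrain = terrain, coefs = scene$coefs,
                 patches = scene$patches, litter_top = litter_top,
                 rough = rough, stems = scene$stems,
                 covered_fraction = scene$covered_fraction,
                 reference_ground = ref),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene: %d litter patches (%.1f%% cover), %d stems, seed %d>\n",
              nrow(x$patches), 100 * x$covered_fraction, nrow(x$stems),
              x$params$seed))
  invisible(x)
}

# evaluate stem axis and surface points; t in [0,1]
.stem_surface_points <- function(stem, t, theta) {
  axis <- c(stem$dx, stem$dy, stem$dz)
  perp <- c(cos(stem$bend_azim), sin(stem$bend_azim), 0)
  perp <- perp - sum(perp * axis) * axis
  nperp <- sqrt(sum(perp^2))
  if (nperp < 1e-12) perp <- c(1, 0, 0) else perp <- perp / nperp
  n2 <- c(axis[2] * perp[3] - axis[3] * perp[2],
          axis[3] * perp[1] - axis[1] * perp[3],
          axis[1] * perp[2] - axis[2] * perp[1])
  cxs <- stem$bx + t * stem$height * axis[1] + stem$bend * t^2 * perp[1]
  cys <- stem$by + t * stem$height * axis[2] + stem$bend * t^2 * perp[2]
  czs <- stem$bz + t * stem$height * axis[3] + stem$bend * t^2 * perp[3]
  cbind(cxs + stem$radius * (cos(theta) * perp[1] + sin(theta) * n2[1]),
        cys + stem$radius * (cos(theta) * perp[2] + sin(theta) * n2[2]),
        czs + stem$radius * (cos(theta) * perp[3] + sin(theta) * n2[3]))
}

#' Sample a labeled point cloud from a synthetic scene
#'
#' Surface-samples the soil, litter-mat top, and stem lateral surfaces at
#' the scene's nominal density (stems at `stem_density_fraction` of it),
#' adds isotropic SfM measurement noise, removes occluded soil points
#' (those under litter or under a stem footprint, each with probability
#' `occlusion_strength`), randomly shuffles, and thins greedily to the
#' minimum spacing. Deterministic given the scene's seed.
#'
#' @param scene a `synthetic_scene` from [generate_scene()].
#' @return a [point_cloud()] with an extra `true_class` integer vector:
#'   1 = ground, 2 = stem (vegetation), 3 = litter. `labels` hold the
#'   binary truth (ground vs nonground).
#' @export
sample_cloud <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  p <- scene$params
  fr <- p$frame
  if (p$point_density_per_m2 * fr$area < 100)
    stop("scene too sparse: density x frame area < 100 points")
  .with_seed(p$seed + 7919L, {
    # soil
    n_g <- round(p$point_density_per_m2 * fr$area)
    gx <- runif(n_g, fr$x0, fr$x0 + fr$width_x)
    gy <- runif(n_g, fr$y0, fr$y0 + fr$width_y)
    gz <- scene$terrain(gx, gy)
    under_litter <- .litter_membership(scene$patches, gx, gy)
    under_stem <- rep(FALSE, n_g)
    if (nrow(scene$stems) > 0) {
      # footprint occlusion within ~3 stem radii of any base
      nn <- FNN::get.knnx(cbind(scene$stems$bx, scene$stems$by),
                          cbind(gx, gy), k = 1L)
      under_stem <- nn$nn.dist[, 1] < 3 * scene$stems$radius[nn$nn.index[, 1]]
    }
    occluded <- (under_litter | under_stem) &
      (runif(n_g) < p$occlusion_strength)
    gx <- gx[!occluded]; gy <- gy[!occluded]; gz <- gz[!occluded]
    ground <- cbind(gx, gy, gz)

    # litter mat top
    litter <- matrix(numeric(0), ncol = 3)
    if (nrow(scene$patches) > 0) {
      n_l <- round(p$point_density_per_m2 * fr$area)
      lx <- runif(n_l, fr$x0, fr$x0 + fr$width_x)
      ly <- runif(n_l, fr$y0, fr$y0 + fr$width_y)
      keep <- .litter_membership(scene$patches, lx, ly)
      lx <- lx[keep]; ly <- ly[keep]
      litter <- cbind(lx, ly, scene$litter_top(lx, ly))
    }

    # stems
    stem_pts <- matrix(numeric(0), ncol = 3)
    if (nrow(scene$stems) > 0) {
      per_stem <- lapply(seq_len(nrow(scene$stems)), function(i) {
        s <- scene$stems[i, ]
        area <- 2 * pi * s$radius * s$height
        m <- max(4L, round(p$point_density_per_m2 * p$stem_density_fraction * area))
        .stem_surface_points(s, runif(m), runif(m, 0, 2 * pi))
      })
      stem_pts <- do.call(rbind, per_stem)
    }

    coords <- rbind(ground, litter, stem_pts)
    true_class <- rep(c(1L, 3L, 2L),
                      c(nrow(ground), nrow(litter), nrow(stem_pts)))
    # SfM measurement noise
    if (p$noise_sd_m > 0)
      coords <- coords + matrix(rnorm(length(coords), 0, p$noise_sd_m),
                                ncol = 3)
    # clip, shuffle, thin
    inside <- coords[, 1] >= fr$x0 & coords[, 1] < fr$x0 + fr$width_x &
              coords[, 2] >= fr$y0 & coords[, 2] < fr$y0 + fr$width_y
    coords <- coords[inside, , drop = FALSE]
    true_class <- true_class[inside]
    perm <- sample.int(nrow(coords))
    coords <- coords[perm, , drop = FALSE]
    true_class <- true_class[perm]
    if (p$min_spacing_m > 0) {
      keep <- cpp_poisson_thin(coords, p$min_spacing_m)
      coords <- coords[keep, , drop = FALSE]
      true_class <- true_class[keep]
    }
    cloud <- point_cloud(coords, labels = ifelse(true_class == 1L, 1L, 2L))
    cloud$true_class <- true_class
    cloud
  })
}

#' True vegetation voxel volume of a scene
#'
#' Voxelizes the analytic litter-top and stem geometry (sampled densely at
#' `edge / 5` resolution, independent of any sampled cloud) and returns
#' occupied voxels times voxel volume. The origin is the frame corner at the
#' terrain minimum.
#'
#' @param scene a `synthetic_scene`.
#' @param edge voxel edge length (m).
#' @return volume in m^3.
#' @export
true_vegetation_volume <- function(scene, edge = 0.005) {
  stopifnot(inherits(scene, "synthetic_scene"), edge > 0)
  fr <- scene$params$frame
  step <- edge / 5
  pts <- list()
  if (nrow(scene$patches) > 0) {
    gx <- seq(fr$x0 + step / 2, fr$x0 + fr$width_x, by = step)
    gy <- seq(fr$y0 + step / 2, fr$y0 + fr$width_y, by = step)
    X <- rep(gx, length(gy)); Y <- rep(gy, each = length(gx))
    keep <- .litter_membership(scene$patches, X, Y)
    X <- X[keep]; Y <- Y[keep]
    pts$litter <- cbind(X, Y, scene$litter_top(X, Y))
  }
  if (nrow(scene$stems) > 0) {
    per_stem <- lapply(seq_len(nrow(scene$stems)), function(i) {
      s <- scene$stems[i, ]
      nt <- max(2L, ceiling(s$height / step))
      ntheta <- max(8L, ceiling(2 * pi * s$radius / step))
      t <- rep((seq_len(nt) - 0.5) / nt, each = ntheta)
      theta <- rep(2 * pi * (seq_len(ntheta) - 0.5) / ntheta, nt)
      .stem_surface_points(s, t, theta)
    })
    pts$stems <- do.call(rbind, per_stem)
  }
  if (length(pts) == 0L) return(0)
  coords <- do.call(rbind, pts)
  inside <- coords[, 1] >= fr$x0 & coords[, 1] < fr$x0 + fr$width_x &
            coords[, 2] >= fr$y0 & coords[, 2] < fr$y0 + fr$width_y
  coords <- coords[inside, , drop = FALSE]
  if (nrow(coords) == 0L) return(0)
  origin <- c(fr$x0, fr$y0, min(scene$reference_ground$z))
  voxel_volume(coords, edge, origin)$volume
}

#' Allometric model used to draw synthetic biomass
#'
#' `total_g = coefficient_g * (volume / reference_volume_m3)^exponent *
#' exp(N(0, noise_sd_log^2))`, split into litter and vegetation components.
#'
#' @param coefficient_g biomass at the reference volume (g), default 800.
#' @param exponent power-law exponent, default 1.
#' @param noise_sd_log lognormal noise sd on the log scale, default 0.5.
#' @param litter_fraction_of_total litter share of total biomass, default 0.6.
#' @param reference_volume_m3 normalizing volume (m^3), default 0.006
#'   (the 5 mm voxel volume of a median litter-covered default scene), so a
#'   median plot draws biomass near the coefficient — the scale of real
#'   destructively harvested cohorts (mean near 900 g).
#' @param veg_split annual : perennial : forb shares of the vegetation
#'   component, default `c(0.8, 0.15, 0.05)`.
#' @return a list of class `allometry_model`.
#' @export
allometry_model <- function(coefficient_g = 800, exponent = 1,
                            noise_sd_log = 0.5,
                            litter_fraction_of_total = 0.6,
                            reference_volume_m3 = 0.006,
                            veg_split = c(0.8, 0.15, 0.05)) {
  stopifnot(coefficient_g > 0, noise_sd_log >= 0,
            litter_fraction_of_total >= 0, litter_fraction_of_total <= 1,
            reference_volume_m3 > 0, length(veg_split) == 3L,
            all(veg_split >= 0), abs(sum(veg_split) - 1) < 1e-9)
  structure(as.list(environment()), class = "allometry_model")
}

#' Draw a synthetic biomass record from a plot volume
#'
#' @param scene_volume vegetation volume of the plot (m^3), > 0.
#' @param model an [allometry_model()].
#' @param seed integer seed.
#' @param plot_id id string for the record.
#' @return a one-row data.frame in the biomass-table schema (see
#'   [read_biomass_table()]).
#' @export
draw_biomass <- function(scene_volume, model = allometry_model(), seed = 1L,
                         plot_id = "p1") {
  stopifnot(inherits(model, "allometry_model"), scene_volume > 0)
  total <- .with_seed(seed,
    model$coefficient_g *
      (scene_volume / model$reference_volume_m3)^model$exponent *
      exp(rnorm(1, 0, model$noise_sd_log)))
  litter <- total * model$litter_fraction_of_total
  veg <- total - litter
  data.frame(plot_id = plot_id,
             annual_g = veg * model$veg_split[1],
             perennial_g = veg * model$veg_split[2],
             forb_g = veg * model$veg_split[3],
             litter_g = litter)
}

#' Draw per-plot scene variation for a cohort
#'
#' Field cohorts vary widely from plot to plot — litter cover, mat thickness
#' and stem density span the range that makes destructively harvested
#' biomass run from tens to thousands of grams. This helper perturbs a base
#' [scene_params()] accordingly: litter cover uniform on (0.2, 0.9), mat
#' thickness on (0.015, 0.045) m, stem count uniform on 0.1-2x the base
#' count. Deterministic in `seed`.
#'
#' @param base_params a [scene_params()] set.
#' @param seed integer; also becomes the returned params' scene seed.
#' @return a `scene_params` set for one plot.
#' @export
vary_scene_params <- function(base_params, seed) {
  sp <- base_params
  sp$seed <- as.integer(seed)
  draws <- .with_seed(seed * 2L + 1L, list(
    cover = runif(1, 0.2, 0.9),
    thickness = runif(1, 0.015, 0.045),
    stems = round(runif(1, 0.1, 2) * base_params$stem_count)))
  sp$litter_cover_fraction <- draws$cover
  sp$litter_thickness_m <- draws$thickness
  sp$stem_count <- as.integer(draws$stems)
  sp
}

#' Write a complete synthetic cohort fixture set
#'
#' Generates `n_plots` scenes (seeds `seed`, `seed + 1`, ...; per-plot
#' variation from [vary_scene_params()] unless `vary_plots = FALSE`), samples
#' each cloud, and writes per-plot PLY files (true binary labels as the label
#' scalar), reference-ground ESRI ASCII grids, and one biomass CSV drawn
#' from the allometric model on each scene's true 5 mm voxel volume.
#'
#' @param out_dir output directory (created if needed).
#' @param n_plots number of plots.
#' @param seed base seed.
#' @param base_params a [scene_params()] set; its seed field is overridden
#'   per plot.
#' @param model an [allometry_model()].
#' @param vary_plots draw plot-to-plot variation (default TRUE).
#' @return invisibly, a data.frame manifest (plot id, paths, true volume).
#' @export
synthesize_cohort <- function(out_dir, n_plots = 10L, seed = 1L,
                              base_params = scene_params(),
                              model = allometry_model(),
                              vary_plots = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  bios <- list()
  for (i in seq_len(n_plots)) {
    pl <- sprintf("plot%03d", i)
    sp <- if (vary_plots) vary_scene_params(base_params, seed + i - 1L)
          else {
            b <- base_params
            b$seed <- as.integer(seed + i - 1L)
            b
          }
    scene <- generate_scene(sp)
    cloud <- sample_cloud(scene)
    tv <- true_vegetation_volume(scene, 0.005)
    ply <- file.path(out_dir, paste0(pl, ".ply"))
    asc <- file.path(out_dir, paste0(pl, "_reference_ground.asc"))
    write_point_cloud(cloud, ply)
    write_terrain_asc(scene$reference_ground, asc)
    bios[[i]] <- draw_biomass(max(tv, 1e-9), model, seed = seed + 10000L + i,
                              plot_id = pl)
    rows[[i]] <- data.frame(plot_id = pl, cloud = basename(ply),
                            reference_ground = basename(asc),
                            true_volume_5mm_m3 = tv,
                            n_points = nrow(cloud$coords))
  }
  bio <- do.call(rbind, bios)
  write_biomass_table(bio, file.path(out_dir, "biomass.csv"))
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "plots.csv"), row.names = FALSE)
  invisible(manifest)
}
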