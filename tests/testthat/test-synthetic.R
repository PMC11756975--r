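# The synthetic scene generator: determinism, coverage, sampling contracts,
# reference volumes, biomass draws.

test_that("scenes are deterministic in the seed", {
  s1 <- generate_scene(small_scene_params(seed = 81))
  s2 <- generate_scene(small_scene_params(seed = 81))
  expect_identical(s1$patches, s2$patches)
  expect_identical(s1$stems, s2$stems)
  expect_identical(s1$coefs, s2$coefs)
  c1 <- sample_cloud(s1)
  c2 <- sample_cloud(s2)
  expect_identical(c1$coords, c2$coords)
  expect_identical(c1$true_class, c2$true_class)
})

test_that("a bare scene labels every point ground", {
  scene <- generate_scene(small_scene_params(seed = 82, stem_count = 0L,
                                             litter_cover_fraction = 0))
  cloud <- sample_cloud(scene)
  expect_true(all(cloud$true_class == 1L))
  expect_true(all(cloud$labels == 1L))
})

test_that("litter cover hits the requested fraction within two percent", {
  for (s in 83:85) {
    scene <- generate_scene(scene_params(seed = s))
    expect_gte(scene$covered_fraction, 0.58)
    expect_lte(scene$covered_fraction, 0.62)
  }
})

test_that("thinning enforces the minimum spacing", {
  scene <- generate_scene(small_scene_params(seed = 86, min_spacing_m = 0.003))
  cloud <- sample_cloud(scene)
  d <- knn_mean_distance(cloud, 1)  # distance to the single nearest neighbor
  expect_gte(min(d), 0.003)
})

test_that("realized density tracks the request below spacing saturation", {
  scene <- generate_scene(scene_params(seed = 87, point_density_per_m2 = 1e5,
                                       stem_count = 0L,
                                       litter_cover_fraction = 0))
  cloud <- sample_cloud(scene)
  realized <- nrow(cloud$coords) / 0.2
  expect_gt(realized, 0.8e5)
  expect_lt(realized, 1.2e5)
})

test_that("full occlusion under litter hides the soil there", {
  scene <- generate_scene(small_scene_params(seed = 88,
                                             occlusion_strength = 1))
  cloud <- sample_cloud(scene)
  gr <- cloud$true_class == 1L
  under <- quadratvol:::.litter_membership(scene$patches,
                                           cloud$coords[gr, 1],
                                           cloud$coords[gr, 2])
  # noise can push a point a hair over a patch border; essentially none remain
  expect_lt(mean(under), 0.01)
})

test_that("the analytic reference volume matches a brute-force cylinder", {
  # one vertical cylinder, radius 2 mm, height 0.10 m, on flat terrain
  p <- scene_params(seed = 89, terrain_relief_m = 0, stem_count = 0L,
                    litter_cover_fraction = 0)
  scene <- generate_scene(p)
  scene$stems <- data.frame(bx = 0.2, by = 0.25, bz = 0,
                            height = 0.10, radius = 0.002,
                            dx = 0, dy = 0, dz = 1, bend = 0, bend_azim = 0)
  edge <- 0.005
  got <- true_vegetation_volume(scene, edge)

  # oracle: rasterize the cylinder's lateral surface on a very fine
  # independent grid (open z-interval: the rim's contact with the cell
  # boundary above has zero surface measure)
  theta <- seq(0, 2 * pi, length.out = 721L)[-1]
  zs <- seq(1e-4, 0.10 - 1e-4, length.out = 500L)
  pts <- cbind(rep(0.2 + 0.002 * cos(theta), length(zs)),
               rep(0.25 + 0.002 * sin(theta), length(zs)),
               rep(zs, each = length(theta)))
  origin <- c(0, 0, min(scene$reference_ground$z))
  key <- unique(paste(floor((pts[, 1] - origin[1]) / edge),
                      floor((pts[, 2] - origin[2]) / edge),
                      floor((pts[, 3] - origin[3]) / edge)))
  expect_equal(got, length(key) * edge^3, tolerance = 1e-12)
})

test_that("reference volumes are zero for empty scenes and nest with edge", {
  bare <- generate_scene(small_scene_params(seed = 90, stem_count = 0L,
                                            litter_cover_fraction = 0))
  expect_equal(true_vegetation_volume(bare, 0.005), 0)

  scene <- generate_scene(small_scene_params(seed = 91))
  v1 <- true_vegetation_volume(scene, 0.005)
  v2 <- true_vegetation_volume(scene, 0.01)
  v4 <- true_vegetation_volume(scene, 0.02)
  expect_lte(v1, v2)
  expect_lte(v2, v4)
})

test_that("the reference ground grid equals the analytic terrain exactly", {
  scene <- generate_scene(small_scene_params(seed = 92))
  cx <- (1:40 - 0.5) * 0.01
  cy <- (1:50 - 0.5) * 0.01
  z <- matrix(scene$terrain(rep(cx, 50), rep(cy, each = 40)), 40, 50)
  expect_equal(scene$reference_ground$z, z, tolerance = 1e-12)
  expect_false(anyNA(scene$reference_ground$z))
})

test_that("biomass draws follow the stated split and close the loop at zero noise", {
  m <- allometry_model(noise_sd_log = 0)
  rec <- draw_biomass(m$reference_volume_m3, m, seed = 1)  # V = Vref -> 800 g
  expect_equal(rec$litter_g, 800 * 0.6)
  expect_equal(rec$annual_g + rec$perennial_g + rec$forb_g, 800 * 0.4)
  expect_equal(rec$annual_g / rec$perennial_g, 0.8 / 0.15, tolerance = 1e-12)

  # noiseless power law is recovered exactly by the log-log fit
  m2 <- allometry_model(noise_sd_log = 0, exponent = 1.2)
  set.seed(93)
  v <- rlnorm(30, log(1e-3), 0.5)
  tot <- vapply(seq_along(v), function(i)
    sum(draw_biomass(v[i], m2, seed = i)[, 2:5]), numeric(1))
  f <- suppressWarnings(fit_log(v, tot))
  expect_equal(f$slope, 1.2, tolerance = 1e-9)

  # cohort scale is in the right ballpark (factor 2 of ~894 g)
  set.seed(94)
  v288 <- rlnorm(288, log(allometry_model()$reference_volume_m3), 0.6)
  tot288 <- vapply(1:288, function(i)
    sum(draw_biomass(v288[i], allometry_model(), seed = 500 + i)[, 2:5]),
    numeric(1))
  expect_gt(mean(tot288), 894 / 2)
  expect_lt(mean(tot288), 894 * 2)
})

test_that("synthesize_cohort writes a complete, readable fixture set", {
  dir <- withr::local_tempdir()
  man <- synthesize_cohort(dir, n_plots = 3L, seed = 95L,
                           base_params = small_scene_params())
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(file.path(dir, man$cloud))))
  expect_true(all(file.exists(file.path(dir, man$reference_ground))))
  bio <- read_biomass_table(file.path(dir, "biomass.csv"))
  expect_equal(sort(bio$plot_id), sort(man$plot_id))
  cl <- read_point_cloud(file.path(dir, man$cloud[1]))
  expect_gt(nrow(cl$coords), 1000)
  expect_true(all(cl$labels %in% 1:2))
})
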