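# Ground-surface fitting, above-surface selection, and surface agreement.

test_that("plane-distributed ground points reproduce the plane exactly", {
  set.seed(51)
  fr <- quadrat_frame()
  n <- 400
  x <- runif(n, -0.05, 0.45); y <- runif(n, -0.05, 0.55)
  flat <- point_cloud(cbind(x, y, 0.1))
  g1 <- fit_ground_surface(flat, fr)
  expect_lt(max(abs(g1$z - 0.1)), 1e-9)
  expect_equal(dim(g1$z), c(40L, 50L))

  tilted <- point_cloud(cbind(x, y, 0.05 * x))
  g2 <- fit_ground_surface(tilted, fr)
  cx <- fr$x0 + (seq_len(40) - 0.5) * 0.01
  expect_equal(g2$z, matrix(rep(0.05 * cx, 50), 40, 50), tolerance = 1e-9)
})

test_that("holes are filled within the range of surrounding points", {
  set.seed(52)
  fr <- quadrat_frame()
  x <- runif(800, 0, 0.4); y <- runif(800, 0, 0.5)
  hole <- sqrt((x - 0.2)^2 + (y - 0.25)^2) < 0.05
  z <- 0.05 + 0.02 * sin(10 * x) * cos(8 * y)
  g <- fit_ground_surface(point_cloud(cbind(x, y, z)[!hole, ]), fr)
  expect_false(anyNA(g$z))
  expect_true(all(g$z >= min(z[!hole]) - 1e-12 & g$z <= max(z[!hole]) + 1e-12))
  # hole cells stay within the range of points surrounding the hole,
  # cross-checked against a nearest-vertex oracle
  ring <- !hole & sqrt((x - 0.2)^2 + (y - 0.25)^2) < 0.12
  hole_cells <- g$z[18:22, 23:27]
  expect_true(all(hole_cells >= min(z[ring]) & hole_cells <= max(z[ring])))
})

test_that("degenerate ground sets are rejected", {
  fr <- quadrat_frame()
  expect_error(fit_ground_surface(point_cloud(cbind(0.1, 0.1, 0)), fr), "3")
  line <- point_cloud(cbind(seq(0, 0.4, length.out = 20), 0.25, 0))
  expect_error(fit_ground_surface(line, fr), "collinear")
})

test_that("above-surface selection applies the strict rule with heights", {
  fr <- quadrat_frame()
  flat <- point_cloud(cbind(runif(50, 0, 0.4), runif(50, 0, 0.5), 0))
  terrain <- fit_ground_surface(flat, fr)
  pc <- point_cloud(rbind(c(0.2, 0.25, 0.05),    # 5 cm above
                          c(0.3, 0.25, -0.001),  # 1 mm below: dropped
                          c(0.1, 0.1, 0)),       # exactly on: dropped
                    labels = c(2L, 2L, 2L))
  res <- points_above_surface(pc, terrain)
  expect_equal(nrow(res$cloud$coords), 1L)
  expect_equal(res$heights, 0.05, tolerance = 1e-9)
})

test_that("above-surface selection matches a per-point loop oracle", {
  set.seed(53)
  fr <- quadrat_frame()
  gx <- runif(500, 0, 0.4); gy <- runif(500, 0, 0.5)
  ground <- point_cloud(cbind(gx, gy, 0.02 * sin(7 * gx) + 0.03 * gy))
  terrain <- fit_ground_surface(ground, fr)
  n <- 2000
  pc <- point_cloud(cbind(runif(n, 0, 0.4), runif(n, 0, 0.5),
                          runif(n, -0.05, 0.2)),
                    labels = sample(1:2, n, TRUE))
  res <- points_above_surface(pc, terrain)
  keep <- logical(n)
  for (i in seq_len(n)) {
    p <- pc$coords[i, ]
    ix <- min(max(floor(p[1] / 0.01), 0), 39) + 1
    iy <- min(max(floor(p[2] / 0.01), 0), 49) + 1
    keep[i] <- pc$labels[i] == 2L && p[3] > terrain$z[ix, iy]
  }
  expect_equal(unname(res$cloud$coords), unname(pc$coords[keep, , drop = FALSE]))
  # output is a subset of the vegetation-labeled points
  expect_true(all(res$cloud$labels == 2L))
})

test_that("terrain grids round-trip through ESRI ASCII", {
  fr <- quadrat_frame()
  set.seed(54)
  g <- fit_ground_surface(point_cloud(cbind(runif(100, 0, .4),
                                            runif(100, 0, .5),
                                            rnorm(100, 0.1, 0.01))), fr)
  f <- withr::local_tempfile(fileext = ".asc")
  write_terrain_asc(g, f)
  back <- read_terrain_asc(f)
  expect_equal(back$z, g$z, tolerance = 1e-6)
  expect_equal(back$cell_size, g$cell_size)
})

test_that("surface agreement reports identity and scaling correctly", {
  v <- c(1, 2, 3, 4, 5) * 1e-3
  a <- surface_agreement(v, v)
  expect_equal(a$mean_abs_rel_diff, 0)
  expect_equal(a$ccc, 1)
  expect_equal(a$tls_slope, 1, tolerance = 1e-12)

  a2 <- surface_agreement(recon_volumes = 2 * v, reference_volumes = v)
  expect_equal(a2$tls_slope, 2, tolerance = 1e-12)
  expect_lt(a2$ccc, 1)
  expect_error(surface_agreement(v, rep(1e-3, 5)), "variance")
})
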