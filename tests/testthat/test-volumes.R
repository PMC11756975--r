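# CHM, convex hull, and voxel-occupancy estimators.

test_that("a uniform canopy over every cell gives exact mean and volume", {
  fr <- quadrat_frame()
  centers <- expand.grid(x = (1:40 - 0.5) * 0.01, y = (1:50 - 0.5) * 0.01)
  chm <- compute_chm(rep(0.30, nrow(centers)), as.matrix(centers), fr)
  expect_equal(chm$mean_height, 0.30, tolerance = 1e-12)
  expect_equal(chm$volume, 0.30 * 0.2, tolerance = 1e-12)
  expect_equal(chm$n_filled, 0L)
})

test_that("IDW gap fill matches hand-computed weights", {
  fr <- quadrat_frame(0, 0, 0.03, 0.03)  # 3 x 3 grid at 0.01 m
  centers <- expand.grid(x = (1:3 - 0.5) * 0.01, y = (1:3 - 0.5) * 0.01)
  h <- c(0.1, 0.2, 0.1,
         0.2, NA, 0.2,
         0.1, 0.2, 0.1)  # corners 0.1, edge-neighbors 0.2, center empty
  keep <- !is.na(h)
  chm <- compute_chm(h[keep], as.matrix(centers)[keep, ], fr)
  w_orth <- 1 / 0.01^2
  w_diag <- 1 / (2 * 0.01^2)
  expected <- (4 * w_orth * 0.2 + 4 * w_diag * 0.1) / (4 * w_orth + 4 * w_diag)
  expect_equal(chm$grid[2, 2], expected, tolerance = 1e-10)
  expect_equal(chm$n_filled, 1L)
})

test_that("cells with no filled neighbor in the window stay empty", {
  fr <- quadrat_frame()
  # a tight cluster in one corner leaves the far corner unreachable in 7x7
  xy <- cbind(runif(200, 0, 0.05), runif(200, 0, 0.05))
  chm <- compute_chm(rep(0.2, 200), xy, fr)
  expect_true(is.na(chm$grid[40, 50]))
  expect_equal(chm$mean_height, mean(chm$grid[!is.na(chm$grid)]))
})

test_that("CHM of zero nonground points is flagged empty", {
  chm <- compute_chm(numeric(0), matrix(numeric(0), ncol = 2), quadrat_frame())
  expect_true(chm$empty)
  expect_equal(chm$volume, 0)
})

test_that("hull volume is exact on closed forms", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_volume(cube)$volume, 1, tolerance = 1e-12)
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(tet)$volume, 1 / 6, tolerance = 1e-12)
})

test_that("degenerate point sets yield volume 0 with a flag", {
  expect_true(convex_hull_volume(rbind(c(0, 0, 0), c(1, 1, 1)))$degenerate)
  coplanar <- cbind(runif(30), runif(30), 0.3)
  res <- convex_hull_volume(coplanar)
  expect_true(res$degenerate)
  expect_equal(res$volume, 0)
})

# independent O(n^4) oracle: a triple is a hull facet iff every other point
# lies on one side of its plane; volume sums tetrahedra to the centroid
hull_volume_bruteforce <- function(P) {
  n <- nrow(P)
  ctr <- colMeans(P)
  vol <- 0
  facets <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
    u <- b - a; v <- c - a
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    d <- drop(P %*% nrm) - sum(nrm * a)
    tol <- 1e-12 * max(abs(d))
    if (all(d <= tol) || all(d >= -tol)) {
      vol <- vol + abs(det(rbind(a - ctr, b - ctr, c - ctr))) / 6
      facets[[length(facets) + 1L]] <- list(a = a, nrm = nrm * sign(sum(nrm * (a - ctr))))
    }
  }
  list(volume = vol, facets = facets)
}

test_that("hull volume matches brute-force facet enumeration and Monte Carlo", {
  set.seed(61)
  P <- cbind(runif(60, 0, 0.4), runif(60, 0, 0.5), runif(60, 0, 0.3))
  got <- convex_hull_volume(P)$volume
  oracle <- hull_volume_bruteforce(P)
  expect_equal(got, oracle$volume, tolerance = 1e-9)

  # Monte-Carlo inclusion with the oracle's halfspaces
  nmc <- 1e6
  inside_total <- 0
  set.seed(62)
  for (chunk in 1:10) {
    Q <- cbind(runif(nmc / 10, 0, 0.4), runif(nmc / 10, 0, 0.5),
               runif(nmc / 10, 0, 0.3))
    inside <- rep(TRUE, nrow(Q))
    for (f in oracle$facets)
      inside <- inside & (drop(Q %*% f$nrm) <= sum(f$nrm * f$a) + 1e-12)
    inside_total <- inside_total + sum(inside)
  }
  mc <- 0.4 * 0.5 * 0.3 * inside_total / nmc
  expect_equal(got, mc, tolerance = 0.01)
})

test_that("hull volume is invariant to permutation and rigid motion", {
  set.seed(63)
  P <- matrix(rnorm(150), ncol = 3)
  v0 <- convex_hull_volume(P)$volume
  expect_equal(convex_hull_volume(P[sample(50), ])$volume, v0,
               tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(sweep(P %*% t(R), 2, c(3, -1, 10), "+"))$volume,
               v0, tolerance = 1e-9 * v0)
})

test_that("voxel occupancy counts cells, not points", {
  one <- voxel_volume(matrix(c(0.123, 0.456, 0.789), ncol = 3), 0.005)
  expect_equal(one$occupied_count, 1L)
  expect_equal(one$volume, 0.005^3)          # 0.125 cm^3
  expect_equal(one$volume * 1e6, 0.125)      # in cm^3

  two <- voxel_volume(rbind(c(0.0011, 0.0012, 0.0013),
                            c(0.0014, 0.0011, 0.0012)), 0.005)
  expect_equal(two$occupied_count, 1L)

  expect_equal(voxel_volume(matrix(numeric(0), ncol = 3), 0.01)$volume, 0)
})

test_that("voxel counts equal the hash-set oracle exactly", {
  set.seed(64)
  P <- matrix(runif(900, -0.3, 0.7), ncol = 3)
  got <- voxel_volume(P, 0.01, origin = c(0, 0, 0))$occupied_count
  key <- unique(paste(floor(P[, 1] / 0.01), floor(P[, 2] / 0.01),
                      floor(P[, 3] / 0.01)))
  expect_equal(got, length(key))
})

test_that("the voxel sweep is monotone under nested edge doubling", {
  set.seed(65)
  P <- matrix(runif(3000, 0, 0.4), ncol = 3)
  sw <- voxel_size_sweep(P, c(0.005, 0.01, 0.02, 0.04), origin = c(0, 0, 0))
  expect_false(is.unsorted(sw$volume_m3))
  # a single point occupies exactly one voxel at every edge
  sw1 <- voxel_size_sweep(matrix(c(0.31, 0.22, 0.13), ncol = 3))
  expect_equal(sw1$volume_m3, sw1$edge_m^3)
})

test_that("a thin dense sheet's voxel volume grows like area x edge", {
  set.seed(66)
  n <- 60000
  P <- cbind(runif(n, 0, 0.4), runif(n, 0, 0.5), 0.1)
  for (e in c(0.005, 0.01, 0.02)) {
    v <- voxel_volume(P, e, c(0, 0, 0))$volume
    expect_equal(v, 0.2 * e, tolerance = 0.15)
  }
})
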