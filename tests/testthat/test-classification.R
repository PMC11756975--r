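# SMRF, curvature, the Gaussian-mixture split, and iterative refinement.

test_that("SMRF keeps a flat noisy plane entirely as ground", {
  set.seed(31)
  n <- 20000
  pc <- point_cloud(cbind(runif(n, 0, 0.4), runif(n, 0, 0.5),
                          runif(n, -0.001, 0.001)))
  labels <- smrf_classify(pc, frame = quadrat_frame())
  expect_true(all(labels == 1L))
})

test_that("SMRF separates a tall block from the plane it stands on", {
  set.seed(32)
  n <- 20000
  plane <- cbind(runif(n, 0, 0.4), runif(n, 0, 0.5), rnorm(n, 0, 3e-4))
  nb <- 3000
  block <- cbind(runif(nb, 0.18, 0.23), runif(nb, 0.22, 0.27),
                 runif(nb, 0.28, 0.30))
  pc <- point_cloud(rbind(plane, block))
  labels <- smrf_classify(pc, frame = quadrat_frame())
  # oracle: true elevation above the z = 0 plane vs the 0.11 m threshold
  oracle <- ifelse(pc$coords[, 3] > 0.11, 2L, 1L)
  expect_gt(mean(labels == oracle), 0.999)
})

test_that("SMRF defaults carry the field parameterization", {
  p <- smrf_params()
  expect_equal(p$elevation_threshold, 0.11)
  expect_equal(p$slope_threshold, 0.1)
  expect_equal(p$elevation_scale, 0.9)
  expect_equal(p$max_window_radius, 10L)
})

test_that("SMRF rejects degenerate extents", {
  pc <- point_cloud(cbind(runif(50, 0, 0.004), runif(50, 0, 0.004), 0))
  expect_error(smrf_classify(pc), "degenerate")
})

test_that("surface variation is 0 on planes and ~1/3 for isotropic scatter", {
  set.seed(33)
  plane <- cbind(runif(500), runif(500), 0)
  cv <- estimate_curvature(point_cloud(plane), 20)
  expect_equal(max(cv), 0)
  expect_true(all(cv >= 0 & cv <= 1 / 3 + 1e-12))

  # isotropic scatter: uniform ball, evaluated away from the boundary
  # (sorted-eigenvalue bias decays like sqrt(2/k), so a large k is used)
  n <- 6000
  u <- matrix(rnorm(3 * n), ncol = 3)
  ball <- u / sqrt(rowSums(u^2)) * runif(n)^(1 / 3)
  cvb <- estimate_curvature(point_cloud(ball), 800)
  central <- order(rowSums(ball^2))[1:20]
  expect_equal(mean(cvb[central]), 1 / 3, tolerance = 0.05 * 3)
})

test_that("surface variation matches an independent eigen-decomposition oracle", {
  set.seed(34)
  pc <- point_cloud(matrix(runif(150), ncol = 3))
  k <- 10L
  cv <- estimate_curvature(pc, k)
  nn <- FNN::get.knn(pc$coords, k = k)$nn.index
  oracle <- vapply(1:50, function(i) {
    nb <- pc$coords[c(i, nn[i, ]), ]
    m <- nrow(nb)
    ev <- sort(eigen(cov(nb) * (m - 1) / m, symmetric = TRUE,
                     only.values = TRUE)$values)
    ev[1] / sum(ev)
  }, numeric(1))
  expect_equal(cv, oracle, tolerance = 1e-10)
})

test_that("the mixture split separates what is separable", {
  # two exact point masses
  s <- gmm_two_component_split(rep(c(0, 1), each = 50), seed = 1)
  expect_equal(s$assignment, rep(c(1L, 2L), each = 50))

  # two well-separated Gaussians, labels known by construction
  set.seed(35)
  v <- c(rnorm(500, 0.01, 0.002), rnorm(500, 0.25, 0.02))
  s2 <- gmm_two_component_split(v, seed = 2)
  truth <- rep(1:2, each = 500)
  expect_gte(mean(s2$assignment == truth), 0.99)
  expect_lt(s2$means[1], s2$means[2])

  # constant input is degenerate
  expect_error(gmm_two_component_split(rep(0.5, 100)), "degenerate")
})

test_that("the mixture fit agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")  # Mclust needs its namespace attached
  set.seed(36)
  v <- c(rnorm(400, 0.02, 0.005), rnorm(600, 0.2, 0.03))
  s <- gmm_two_component_split(v, seed = 3)
  m <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(s$means), sort(as.numeric(m$parameters$mean)),
               tolerance = 0.01)
  agree <- mean(s$assignment == m$classification)
  expect_gt(max(agree, 1 - agree), 0.99)
})

test_that("refinement improves vegetation IoU on a litter-covered scene", {
  scene <- generate_scene(small_scene_params(seed = 41))
  cloud <- sample_cloud(scene)
  smrf_lab <- smrf_classify(cloud, frame = quadrat_frame())
  res <- iterative_refine(cloud, smrf_lab, seed = 41)
  expect_gt(vegetation_iou(res$labels, cloud$true_class),
            vegetation_iou(smrf_lab, cloud$true_class))
  # additive merge: points only move ground -> vegetation
  expect_true(all(res$labels[smrf_lab == 2L] == 2L))
  # volume trace is non-decreasing
  expect_false(is.unsorted(res$vegetation_volume_trace))
})

test_that("refinement leaves bare terrain untouched", {
  scene <- generate_scene(small_scene_params(seed = 42, stem_count = 0L,
                                             litter_cover_fraction = 0))
  cloud <- sample_cloud(scene)
  expect_true(all(cloud$true_class == 1L))
  smrf_lab <- smrf_classify(cloud, frame = quadrat_frame())
  res <- iterative_refine(cloud, smrf_lab, seed = 42)
  expect_lte(mean(res$labels != smrf_lab), 0.01)
})

test_that("classification is reproducible bit-for-bit under a fixed seed", {
  scene <- generate_scene(small_scene_params(seed = 43))
  cloud <- sample_cloud(scene)
  smrf_lab <- smrf_classify(cloud, frame = quadrat_frame())
  r1 <- iterative_refine(cloud, smrf_lab, seed = 7)
  r2 <- iterative_refine(cloud, smrf_lab, seed = 7)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$vegetation_volume_trace, r2$vegetation_volume_trace)
})

test_that("the curvature feature also improves IoU on litter scenes", {
  scene <- generate_scene(small_scene_params(seed = 44))
  cloud <- sample_cloud(scene)
  smrf_lab <- smrf_classify(cloud, frame = quadrat_frame())
  # the curvature mixture is less separable than the elevation one, so the
  # bimodality guard is relaxed for this mode
  res <- iterative_refine(cloud, smrf_lab,
                          refine_params(feature = "curvature",
                                        neighbor_counts = c(30L, 60L),
                                        min_separation = 1.5),
                          seed = 44)
  expect_gt(vegetation_iou(res$labels, cloud$true_class),
            vegetation_iou(smrf_lab, cloud$true_class))
})

test_that("the default stopping rule mirrors the 5% improvement criterion", {
  expect_equal(refine_params()$improvement_fraction, 0.05)
  expect_equal(refine_params()$neighbor_counts, c(50L, 200L))
})
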