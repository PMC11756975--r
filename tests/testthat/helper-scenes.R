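# Shared fixtures, built in code.

# small, fast scene parameters for unit tests (acceptance tests use defaults)
small_scene_params <- function(seed = 1L, point_density_per_m2 = 2e5,
                               stem_count = 60L, ...) {
  scene_params(seed = seed, point_density_per_m2 = point_density_per_m2,
               stem_count = stem_count, ...)
}

# classification metrics against the generator's exact labels
ground_recall <- function(labels, true_class) {
  sum(labels == 1L & true_class == 1L) / sum(true_class == 1L)
}
vegetation_iou <- function(labels, true_class) {
  truth_veg <- true_class != 1L
  sum(labels == 2L & truth_veg) / sum(labels == 2L | truth_veg)
}

# The acceptance suite: 20 scenes at default parameters, classified and
# measured once per test session (several acceptance properties share it).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_suite <- function(n_scenes = 20L) {
  key <- paste0("suite", n_scenes)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  frame <- quadrat_frame()
  nested_edges <- c(0.0025, 0.005, 0.01, 0.02, 0.04)
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- generate_scene(scene_params(seed = 100L + i))
    cloud <- sample_cloud(scene)
    smrf_lab <- smrf_classify(cloud, frame = frame)
    ref <- iterative_refine(cloud, smrf_lab, seed = 100L + i)
    terrain <- fit_ground_surface(
      subset_cloud(cloud, ref$labels == 1L), frame)
    above_recon <- points_above_surface(cloud, terrain, labels = ref$labels)
    above_true <- points_above_surface(cloud, scene$reference_ground,
                                       labels = ref$labels)
    origin <- c(frame$x0, frame$y0, min(terrain$z))
    origin_true <- c(frame$x0, frame$y0, min(scene$reference_ground$z))
    veg <- subset_cloud(cloud, ref$labels == 2L)
    nested <- vapply(nested_edges, function(e)
      voxel_volume(veg, e, origin)$volume, numeric(1))
    rows[[i]] <- list(
      seed = 100L + i,
      has_litter = nrow(scene$patches) > 0L,
      smrf_iou = vegetation_iou(smrf_lab, cloud$true_class),
      iou = vegetation_iou(ref$labels, cloud$true_class),
      recall = ground_recall(ref$labels, cloud$true_class),
      volume_trace = ref$vegetation_volume_trace,
      vol_recon = voxel_volume(above_recon$cloud, 0.005, origin)$volume,
      vol_reference = voxel_volume(above_true$cloud, 0.005, origin_true)$volume,
      nested_volumes = nested)
  }
  .acceptance_cache[[key]] <- rows
  rows
}
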