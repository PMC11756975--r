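## End-to-end per-plot and cohort orchestration.

#' Pipeline configuration
#'
#' Bundles every stage's parameters with the field defaults: 11 cm SMRF
#' elevation threshold, slope 0.1, scale 0.9, window radius 10; mixture
#' refinement with 50 then 200 neighbors and the 5% volume-improvement stop;
#' 0.01 m grids with 7 x 7 IDW gap fill; voxel edges 2-100 mm; 90% power
#' screening at alpha 0.05.
#'
#' @param frame a [quadrat_frame()].
#' @param denoise_k,denoise_multiplier statistical outlier filter settings.
#' @param smrf an [smrf_params()] set.
#' @param refine a [refine_params()] set.
#' @param chm a [chm_params()] set.
#' @param voxel_edges ascending voxel edge lengths (m).
#' @param alpha,min_power power-screening settings.
#' @param seed integer seed for the mixture initialization.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(frame = quadrat_frame(),
                            denoise_k = 10L, denoise_multiplier = 1,
                            smrf = smrf_params(), refine = refine_params(),
                            chm = chm_params(),
                            voxel_edges = default_voxel_edges(),
                            alpha = 0.05, min_power = 0.90, seed = 1L) {
  stopifnot(all(voxel_edges > 0), !is.unsorted(voxel_edges))
  structure(as.list(environment()), class = "pipeline_config")
}

.voxel_col <- function(edge) sprintf("voxel_%gmm", edge * 1000)

#' Run the full workflow on one plot
#'
#' Clip to frame, statistical outlier removal, SMRF classification, iterative
#' Gaussian-mixture refinement, ground-surface fit, above-surface selection,
#' then the three volume estimators (the vegetation subset is denoised once
#' more before the hull and voxel computations). When a reference ground grid
#' is supplied, the 5 mm above-surface voxel volume is also computed against
#' it, enabling the surface-agreement comparison.
#'
#' @param cloud a [point_cloud()] or a path readable by [read_point_cloud()].
#' @param config a [pipeline_config()].
#' @param reference_ground optional `terrain_grid` of the true (bare-soil)
#'   surface.
#' @param plot_id id string for the output row.
#' @return a list of class `plot_result`: `volumes` (one-row data.frame),
#'   `classification` (the `classification_result`), `terrain`, `cloud`
#'   (labeled, denoised), `heights` (above-ground heights of the
#'   above-surface points), and `log` (per-stage point counts).
#' @export
run_plot <- function(cloud, config = pipeline_config(),
                     reference_ground = NULL, plot_id = "plot") {
  if (is.character(cloud)) cloud <- read_point_cloud(cloud)
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "pipeline_config"))
  log <- list(n_input = nrow(cloud$coords))

  cloud <- clip_to_frame(cloud, config$frame)
  log$n_clipped <- nrow(cloud$coords)
  if (log$n_clipped <= config$denoise_k + 1L)
    stop("too few points inside the frame (", log$n_clipped, ")")

  den <- statistical_outlier_filter(cloud, k = config$denoise_k,
                                    std_multiplier = config$denoise_multiplier)
  cloud <- den$cloud
  log$n_denoised <- nrow(cloud$coords)

  smrf_labels <- smrf_classify(cloud, config$smrf, frame = config$frame)
  log$n_smrf_ground <- sum(smrf_labels == 1L)
  cls <- iterative_refine(cloud, smrf_labels, config$refine, seed = config$seed)
  cloud$labels <- cls$labels
  log$n_ground <- sum(cls$labels == 1L)
  log$n_vegetation <- sum(cls$labels == 2L)

  ground <- subset_cloud(cloud, cls$labels == 1L)
  terrain <- fit_ground_surface(ground, config$frame, config$smrf$cell_size)
  above <- points_above_surface(cloud, terrain)
  log$n_above_surface <- nrow(above$cloud$coords)

  veg <- subset_cloud(cloud, cls$labels == 2L)
  if (nrow(veg$coords) > config$denoise_k + 1L) {
    veg <- statistical_outlier_filter(veg, k = config$denoise_k,
                                      std_multiplier = config$denoise_multiplier)$cloud
  }

  chm <- compute_chm(above$heights, above$cloud$coords[, 1:2, drop = FALSE],
                     config$frame, config$chm)
  hull_all <- convex_hull_volume(veg)
  hull_above <- convex_hull_volume(above$cloud)

  origin <- c(config$frame$x0, config$frame$y0, min(terrain$z))
  sweep_tab <- voxel_size_sweep(veg, config$voxel_edges, origin)

  vol_above_recon <- voxel_volume(above$cloud, 0.005, origin)$volume
  vol_above_ref <- NA_real_
  if (!is.null(reference_ground)) {
    above_ref <- points_above_surface(cloud, reference_ground)
    vol_above_ref <- voxel_volume(above_ref$cloud, 0.005,
                                  c(config$frame$x0, config$frame$y0,
                                    min(reference_ground$z)))$volume
  }

  row <- data.frame(plot_id = plot_id,
                    chm_mean_height_m = chm$mean_height,
                    chm_volume = chm$volume,
                    hull_volume = hull_all$volume,
                    hull_above_volume = hull_above$volume,
                    voxel5mm_above_recon = vol_above_recon,
                    voxel5mm_above_reference = vol_above_ref)
  for (i in seq_len(nrow(sweep_tab)))
    row[[.voxel_col(sweep_tab$edge_m[i])]] <- sweep_tab$volume_m3[i]

  structure(list(volumes = row, classification = cls, terrain = terrain,
                 cloud = cloud, heights = above$heights, log = log),
            class = "plot_result")
}

#' Run the cohort workflow over a directory of plots
#'
#' Expects per-plot cloud files (and optionally `<plot>_reference_ground.asc`
#' grids) plus a biomass CSV. Each plot runs in isolation: a failing plot is
#' recorded in the manifest with its stage and reason, and the run continues.
#' Volumes are joined with biomass and every estimator x biomass-component x
#' {linear, log} combination is fitted and power-screened; the voxel-size
#' Wilcoxon table and (when reference grids exist) the surface-agreement
#' report are produced.
#'
#' @param plots_dir directory with cloud files (`.ply`/`.las`/`.xyz`).
#' @param biomass_csv path to the biomass table.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for `volumes.csv`, `report.csv`,
#'   `wilcoxon.csv`, `agreement.csv` and `manifest.json`.
#' @param group_by optional column names in the biomass table to fit within,
#'   in addition to the pooled fit.
#' @return a list of class `cohort_result`: `volumes`, `report`, `wilcoxon`,
#'   `agreement` (or NULL), `manifest`.
#' @export
run_cohort <- function(plots_dir, biomass_csv, config = pipeline_config(),
                       out_dir = NULL, group_by = NULL) {
  files <- list.files(plots_dir, pattern = "\\.(ply|las|xyz)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L) stop("no point-cloud files in ", plots_dir)
  bio <- read_biomass_table(biomass_csv)

  manifest <- list()
  vol_rows <- list()
  for (f in files) {
    pl <- tools::file_path_sans_ext(basename(f))
    ref_path <- file.path(plots_dir, paste0(pl, "_reference_ground.asc"))
    ref <- if (file.exists(ref_path)) read_terrain_asc(ref_path) else NULL
    res <- tryCatch(run_plot(f, config, reference_ground = ref, plot_id = pl),
                    error = function(e) e)
    if (inherits(res, "error")) {
      manifest[[pl]] <- list(plot_id = pl, status = "failed",
                             reason = conditionMessage(res))
    } else {
      manifest[[pl]] <- list(plot_id = pl, status = "ok",
                             n_points = res$log$n_denoised,
                             n_vegetation = res$log$n_vegetation)
      vol_rows[[pl]] <- res$volumes
    }
  }
  volumes <- do.call(rbind, vol_rows)
  if (is.null(volumes) || nrow(volumes) < 3L)
    stop("fewer than 3 plots succeeded; cannot fit cohort models")

  merged <- merge(volumes, bio, by = "plot_id")
  unmatched <- setdiff(volumes$plot_id, bio$plot_id)
  if (length(unmatched))
    warning("plots without biomass rows excluded: ",
            paste(unmatched, collapse = ", "))

  estimators <- c("chm_volume", "hull_volume", "hull_above_volume",
                  grep("^voxel_", names(volumes), value = TRUE))
  components <- c("annual_g", "perennial_g", "forb_g", "litter_g",
                  "vegetation_total_g", "total_g")
  groups <- list(all = rep(TRUE, nrow(merged)))
  for (g in group_by) {
    if (!g %in% names(merged)) stop("group_by column not found: ", g)
    for (lev in unique(merged[[g]]))
      groups[[paste0(g, "=", lev)]] <- merged[[g]] == lev
  }

  report <- list()
  for (gname in names(groups)) {
    sel <- merged[groups[[gname]], , drop = FALSE]
    if (nrow(sel) < 3L) next
    for (est in estimators) for (comp in components) for (form in c("linear", "log")) {
      fit <- tryCatch({
        r <- if (form == "linear") fit_linear(sel[[est]], sel[[comp]])
             else fit_log(sel[[est]], sel[[comp]])
        power_screen(r, config$alpha, config$min_power)
      }, error = function(e) NULL)
      if (is.null(fit)) next
      report[[length(report) + 1L]] <-
        data.frame(group = gname, estimator = est, component = comp,
                   form = form, n = fit$n, slope = fit$slope,
                   intercept = fit$intercept, r_squared = fit$r_squared,
                   rmse_g = fit$rmse_g, f_squared = fit$f_squared,
                   achieved_power = fit$achieved_power,
                   significant = fit$significant)
    }
  }
  report <- do.call(rbind, report)

  vox_cols <- grep("^voxel_", names(volumes), value = TRUE)
  wilcox <- if (length(vox_cols) >= 2L && nrow(volumes) >= 6L)
    compare_voxel_distributions(as.matrix(volumes[vox_cols])) else NULL

  agreement <- NULL
  have_ref <- !is.na(volumes$voxel5mm_above_reference)
  if (sum(have_ref) >= 3L)
    agreement <- surface_agreement(volumes$voxel5mm_above_recon[have_ref],
                                   volumes$voxel5mm_above_reference[have_ref])

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(volumes, file.path(out_dir, "volumes.csv"), row.names = FALSE)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    if (!is.null(wilcox))
      write.csv(wilcox, file.path(out_dir, "wilcoxon.csv"), row.names = FALSE)
    if (!is.null(agreement))
      write.csv(data.frame(n = agreement$n,
                           mean_abs_rel_diff = agreement$mean_abs_rel_diff,
                           r_squared = agreement$r_squared,
                           tls_slope = agreement$tls_slope,
                           tls_intercept = agreement$tls_intercept,
                           ccc = agreement$ccc),
                file.path(out_dir, "agreement.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(plots_in = length(files),
           plots_succeeded = sum(vapply(manifest, function(m)
             m$status == "ok", logical(1))),
           plots_failed = sum(vapply(manifest, function(m)
             m$status == "failed", logical(1))),
           plots = manifest),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  structure(list(volumes = volumes, report = report, wilcoxon = wilcox,
                 agreement = agreement, manifest = manifest),
            class = "cohort_result")
}
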