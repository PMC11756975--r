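## Iterative Gaussian-mixture refinement of the SMRF ground class.
##
## A thick litter mat passes the morphological filter's 11 cm elevation test,
## so the ground class still holds vegetation biomass. Litter and stems are
## geometrically rougher than mineral soil, so their local surface variation
## (curvature proxy) separates from the soil's: a two-component 1-D Gaussian
## mixture on the curvature of the current ground class is fitted, the
## high-curvature component is merged into vegetation, and the step is kept
## whenever it grows the vegetation voxel volume by more than the improvement
## fraction. Points only ever move ground -> vegetation.

# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Local surface variation ("curvature") per point
#'
#' For each point, the eigenvalues `l1 >= l2 >= l3 >= 0` of the covariance of
#' its neighborhood (the point plus its `k` nearest neighbors) give the
#' surface variation `l3 / (l1 + l2 + l3)`: 0 for a perfect plane, up to 1/3
#' for fully isotropic scatter.
#'
#' @param cloud a [point_cloud()].
#' @param k neighborhood size, `3 <= k < N`.
#' @return numeric vector in `[0, 1/3]`, length N.
#' @export
estimate_curvature <- function(cloud, k = 50L) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 3L)
  n <- nrow(cloud$coords)
  if (n <= k) stop("estimate_curvature needs more than k = ", k, " points, got ", n)
  cpp_surface_variation(cloud$coords, as.integer(k))
}

#' Two-component 1-D Gaussian mixture split
#'
#' Fits a two-component univariate Gaussian mixture by
#' expectation-maximization (seeded k-means initialization, at most 100 EM
#' iterations, log-likelihood tolerance 1e-6) and assigns each value to its
#' maximum-posterior component; ties go to the low-mean component. The
#' component with the lower mean is reported as component 1 (ground-like).
#'
#' @param values numeric vector with at least two distinct values.
#' @param seed integer seed for the k-means initialization.
#' @return a list with `assignment` (1 = low component, 2 = high), `means`,
#'   `sds`, `weights` (all ordered low, high), `separation` (Ashman's D,
#'   `|m2 - m1| / sqrt((s1^2 + s2^2) / 2)`), and `iterations`.
#' @export
gmm_two_component_split <- function(values, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L || diff(range(values)) <= 0)
    stop("gmm_two_component_split: all values identical; ",
         "mixture is degenerate, skip refinement")
  km <- .with_seed(seed, kmeans(values, centers = 2L, nstart = 3L, iter.max = 50L))
  ord <- order(km$centers)
  mu <- as.numeric(km$centers[ord])
  grp <- match(km$cluster, ord)
  s2 <- vapply(1:2, function(g) {
    v <- var(values[grp == g])
    if (!is.finite(v) || v <= 0) var(values) * 1e-4 + 1e-300 else v
  }, numeric(1))
  w <- tabulate(grp, 2L) / n
  floor_var <- max(var(values), 1e-300) * 1e-10
  ll_old <- -Inf
  iterations <- 0L
  for (it in seq_len(100L)) {
    iterations <- it
    d1 <- w[1] * dnorm(values, mu[1], sqrt(s2[1]))
    d2 <- w[2] * dnorm(values, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (n1 <= 0 || n2 <= 0) break
    mu <- c(sum(r1 * values) / n1, sum(r2 * values) / n2)
    s2 <- pmax(c(sum(r1 * (values - mu[1])^2) / n1,
                 sum(r2 * (values - mu[2])^2) / n2), floor_var)
    w <- c(n1, n2) / n
    if (is.finite(ll_old) && abs(ll - ll_old) < 1e-6) break
    ll_old <- ll
  }
  if (mu[1] > mu[2]) {  # keep component 1 = low mean
    mu <- rev(mu); s2 <- rev(s2); w <- rev(w)
  }
  post_low <- w[1] * dnorm(values, mu[1], sqrt(s2[1]))
  post_high <- w[2] * dnorm(values, mu[2], sqrt(s2[2]))
  assignment <- ifelse(post_high > post_low, 2L, 1L)  # tie -> low component
  list(assignment = assignment, means = mu, sds = sqrt(s2), weights = w,
       separation = abs(mu[2] - mu[1]) / sqrt((s2[1] + s2[2]) / 2),
       iterations = iterations)
}

#' Refinement parameter set
#'
#' Two mixture features are available. `"elevation"` (default) is the height
#' of each ground-class point above the minimum-elevation raster of the
#' current ground class (per-cell minimum, nearest-neighbor inpainted) — the
#' same robust surface the morphological filter reasons about; soil collapses
#' to a sharp mode near zero while the litter mat sits one mat-thickness
#' higher, and on bare soil the feature is unimodal so refinement stops with
#' labels untouched. `"curvature"` is the local surface variation at
#' `neighbor_counts[it]` neighbors; it separates smooth soil from rough
#' litter but is blurred wherever a neighborhood straddles a litter border.
#'
#' @param neighbor_counts neighborhood sizes per pass for the curvature
#'   feature; the first pass uses `neighbor_counts[1]` on the SMRF ground
#'   class, each later pass runs on the ground output of the previous pass
#'   (the last count is reused once the list is exhausted). Defaults
#'   `c(50, 200)`.
#' @param improvement_fraction minimum relative vegetation-volume gain for a
#'   refinement pass to be kept (default 0.05).
#' @param volume_voxel_edge voxel edge (m) used for the volume criterion.
#' @param feature mixture feature: `"elevation"` (height above the ground
#'   class's minimum surface, default) or `"curvature"` (surface variation).
#' @param surface_cell_m raster cell (m) for the elevation feature's minimum
#'   surface, default 0.01.
#' @param max_iterations safety cap on refinement passes.
#' @param min_gap_m elevation mode only: minimum gap (m) between the fitted
#'   component means for a move to be considered. A two-component EM fit
#'   always splits something, even a single population; on bare soil the
#'   split means differ by the noise scale (a millimeter or two), while
#'   litter sits a mat-thickness (~3 cm) above the soil mode. The default
#'   0.004 m is an order of magnitude above the sensor noise and well under
#'   any litter mat. Below the gap, refinement stops with labels unchanged.
#' @param min_separation curvature mode only: minimum Ashman D
#'   (`|m2 - m1| / sqrt((s1^2 + s2^2)/2)`) between the fitted components;
#'   below it the mixture is treated as unimodal and refinement stops.
#' @return a list of class `refine_params`.
#' @export
refine_params <- function(neighbor_counts = c(50L, 200L),
                          improvement_fraction = 0.05,
                          volume_voxel_edge = 0.005,
                          feature = c("elevation", "curvature"),
                          surface_cell_m = 0.01,
                          max_iterations = 10L,
                          min_gap_m = 0.004,
                          min_separation = 2) {
  feature <- match.arg(feature)
  stopifnot(all(neighbor_counts >= 3L), improvement_fraction > 0,
            improvement_fraction < 1, volume_voxel_edge > 0,
            surface_cell_m > 0, max_iterations >= 1L, min_gap_m >= 0,
            min_separation >= 0)
  structure(list(neighbor_counts = as.integer(neighbor_counts),
                 improvement_fraction = improvement_fraction,
                 volume_voxel_edge = volume_voxel_edge,
                 feature = feature,
                 surface_cell_m = surface_cell_m,
                 max_iterations = as.integer(max_iterations),
                 min_gap_m = min_gap_m,
                 min_separation = min_separation),
            class = "refine_params")
}

# height of each point above the per-cell minimum-z raster of the same
# points (empty cells impossible; cells are defined by the points)
.height_above_min_surface <- function(coords, cell) {
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- min(x); y0 <- min(y)
  nx <- max(1L, floor((max(x) - x0) / cell) + 1L)
  ix <- pmin(floor((x - x0) / cell), nx - 1L)
  iy <- floor((y - y0) / cell)
  id <- ix + nx * iy
  o <- order(id, z)
  first <- o[!duplicated(id[o])]
  zmin <- z[first][match(id, id[first])]
  z - zmin
}

#' Iteratively refine the SMRF ground class with Gaussian mixtures
#'
#' Each pass computes the mixture feature on the current ground class, splits
#' it with [gmm_two_component_split()], and proposes moving the
#' high-component points into vegetation. The proposal is committed when the
#' mixture is genuinely two populations (component means at least `min_gap_m`
#' apart for the elevation feature; Ashman D at least `min_separation` for
#' curvature) and the vegetation voxel volume (at `volume_voxel_edge`) grows
#' by more than `improvement_fraction`; otherwise labels revert and iteration
#' stops. Vegetation therefore grows monotonically and the volume trace is
#' non-decreasing.
#'
#' @param cloud a [point_cloud()].
#' @param smrf_labels integer labels from [smrf_classify()] (1/2).
#' @param refine a [refine_params()] set.
#' @param seed integer seed passed to the mixture initialization.
#' @return a list of class `classification_result`: `labels` (1 = ground,
#'   2 = vegetation), `iterations_run` (number of mixture evaluations),
#'   `committed` (number of kept passes), and `vegetation_volume_trace`
#'   (m^3; the SMRF volume followed by each committed pass's volume).
#' @export
iterative_refine <- function(cloud, smrf_labels, refine = refine_params(),
                             seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$coords)
  stopifnot(length(smrf_labels) == n, all(smrf_labels %in% 1:2))
  labels <- as.integer(smrf_labels)
  origin <- if (n > 0) apply(cloud$coords, 2L, min) else c(0, 0, 0)
  edge <- refine$volume_voxel_edge
  veg_vol <- function(lab) {
    idx <- lab == 2L
    if (!any(idx)) return(0)
    cpp_voxel_count(cloud$coords[idx, , drop = FALSE], edge, origin) * edge^3
  }
  v_cur <- veg_vol(labels)
  trace <- v_cur
  evaluations <- 0L
  committed <- 0L
  for (it in seq_len(refine$max_iterations)) {
    k <- refine$neighbor_counts[min(it, length(refine$neighbor_counts))]
    gidx <- which(labels == 1L)
    if (length(gidx) <= k + 1L) break
    ground <- subset_cloud(cloud, gidx)
    feat <- switch(refine$feature,
                   curvature = estimate_curvature(ground, k),
                   elevation = .height_above_min_surface(ground$coords,
                                                         refine$surface_cell_m))
    split <- tryCatch(gmm_two_component_split(feat, seed = seed + it),
                      error = function(e) NULL)
    evaluations <- evaluations + 1L
    if (is.null(split)) break                      # degenerate mixture
    # single-population guard, in the feature's own units
    if (refine$feature == "elevation") {
      if (diff(split$means) < refine$min_gap_m) break   # noise-scale split
    } else {
      if (split$separation < refine$min_separation) break  # unimodal feature
    }
    move <- gidx[split$assignment == 2L]
    if (length(move) == 0L || length(move) == length(gidx)) break
    cand <- labels
    cand[move] <- 2L
    v_new <- veg_vol(cand)
    gain <- if (v_cur > 0) (v_new - v_cur) / v_cur else if (v_new > 0) Inf else 0
    if (gain <= refine$improvement_fraction) break  # discard, terminate
    labels <- cand
    v_cur <- v_new
    trace <- c(trace, v_new)
    committed <- committed + 1L
  }
  structure(list(labels = labels, iterations_run = evaluations,
                 committed = committed, vegetation_volume_trace = trace),
            class = "classification_result")
}
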