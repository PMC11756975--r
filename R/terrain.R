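## Terrain surface fitting from ground-classified points.

#' Fit an interpolated ground surface
#'
#' Evaluates a triangulated linear interpolation of the ground points at the
#' centers of a regular grid covering the quadrat frame (40 x 50 cells at the
#' 0.01 m default). Cells outside the convex hull of the ground points are
#' filled by nearest-neighbor extrapolation, so the grid has no empty cells.
#' Linear interpolation reproduces planes exactly.
#'
#' Very dense ground sets are decimated before triangulation: each
#' `decimate_cell`-sized cell contributes its median-elevation point (a
#' subset of the input, so plane exactness is preserved).
#'
#' @param ground_points a [point_cloud()] holding only ground points, or any
#'   cloud together with `labels == 1` marking ground.
#' @param frame a [quadrat_frame()].
#' @param cell_size grid resolution (m), default 0.01.
#' @param decimate_cap decimate when more ground points than this (default
#'   50000).
#' @param decimate_cell decimation cell size (m), default 0.005.
#' @return an object of class `terrain_grid`: `x0`, `y0`, `cell_size`, and
#'   `z` (an `nx x ny` matrix of elevations, x indexing rows).
#' @export
fit_ground_surface <- function(ground_points, frame, cell_size = 0.01,
                               decimate_cap = 50000L, decimate_cell = 0.005) {
  stopifnot(inherits(ground_points, "point_cloud"),
            inherits(frame, "quadrat_frame"), cell_size > 0)
  pts <- ground_points$coords
  if (!is.null(ground_points$labels) && any(ground_points$labels != 1L))
    pts <- pts[ground_points$labels == 1L, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("fit_ground_surface needs at least 3 ground points, got ", nrow(pts))
  if (qr(cbind(pts[, 1] - mean(pts[, 1]), pts[, 2] - mean(pts[, 2])),
         tol = 1e-10)$rank < 2L)
    stop("ground points are collinear in xy; cannot triangulate a surface")
  if (nrow(pts) > decimate_cap) {
    cell <- paste(floor(pts[, 1] / decimate_cell),
                  floor(pts[, 2] / decimate_cell))
    o <- order(cell, pts[, 3])
    grp <- cell[o]
    runs <- rle(grp)$lengths
    ends <- cumsum(runs)
    mid <- ends - (runs - 1L) %/% 2L   # median-z representative per cell
    pts <- pts[o[mid], , drop = FALSE]
  }
  nx <- max(1L, round(frame$width_x / cell_size))
  ny <- max(1L, round(frame$width_y / cell_size))
  cx <- frame$x0 + (seq_len(nx) - 0.5) * cell_size
  cy <- frame$y0 + (seq_len(ny) - 0.5) * cell_size
  qx <- rep(cx, ny); qy <- rep(cy, each = nx)
  z <- matrix(.fill_surface(pts[, 1], pts[, 2], pts[, 3], qx, qy), nx, ny)
  structure(list(x0 = frame$x0, y0 = frame$y0, cell_size = cell_size, z = z),
            class = "terrain_grid")
}

#' @export
print.terrain_grid <- function(x, ...) {
  cat(sprintf("<terrain_grid: %d x %d cells at %.4g m, z in [%.4g, %.4g] m>\n",
              nrow(x$z), ncol(x$z), x$cell_size, min(x$z), max(x$z)))
  invisible(x)
}

# terrain elevation under arbitrary (x, y); cells are half-open, queries
# outside the grid clamp to the border cell
.terrain_at <- function(terrain, x, y) {
  ix <- pmin(pmax(floor((x - terrain$x0) / terrain$cell_size), 0),
             nrow(terrain$z) - 1L)
  iy <- pmin(pmax(floor((y - terrain$y0) / terrain$cell_size), 0),
             ncol(terrain$z) - 1L)
  terrain$z[cbind(ix + 1L, iy + 1L)]
}

#' Select vegetation points above the fitted ground surface
#'
#' Returns the vegetation-labeled points whose elevation strictly exceeds
#' the terrain elevation of their containing grid cell; the height above
#' ground is attached per point. Points falling outside the terrain grid's
#' frame are excluded (their count is reported).
#'
#' @param cloud a labeled [point_cloud()].
#' @param terrain a `terrain_grid` from [fit_ground_surface()].
#' @param labels optional labels overriding `cloud$labels`.
#' @return a list: `cloud` (the retained [point_cloud()]), `heights`
#'   (m above ground, aligned with `cloud`), `n_outside_frame`.
#' @export
points_above_surface <- function(cloud, terrain, labels = cloud$labels) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(terrain, "terrain_grid"))
  if (is.null(labels)) stop("points_above_surface needs labels")
  if (anyNA(terrain$z)) stop("terrain grid has empty cells")
  veg <- which(labels == 2L)
  x <- cloud$coords[veg, 1]; y <- cloud$coords[veg, 2]; z <- cloud$coords[veg, 3]
  nx <- nrow(terrain$z); ny <- ncol(terrain$z)
  inside <- x >= terrain$x0 & x < terrain$x0 + nx * terrain$cell_size &
            y >= terrain$y0 & y < terrain$y0 + ny * terrain$cell_size
  n_out <- sum(!inside)
  if (n_out > 0)
    warning(n_out, " vegetation point(s) outside the terrain frame were excluded")
  veg <- veg[inside]
  h <- cloud$coords[veg, 3] -
    .terrain_at(terrain, cloud$coords[veg, 1], cloud$coords[veg, 2])
  above <- h > 0
  list(cloud = subset_cloud(cloud, veg[above]), heights = h[above],
       n_outside_frame = n_out)
}

#' Agreement between reconstructed- and reference-surface volumes
#'
#' Compares per-plot vegetation volumes computed above a reconstructed
#' (classified) ground surface against volumes above a reference (bare-soil)
#' surface: mean absolute relative difference, ordinary least squares R^2,
#' total-least-squares line, and Lin's concordance correlation coefficient.
#'
#' @param recon_volumes,reference_volumes paired per-plot volumes (m^3),
#'   length >= 3.
#' @return a list of class `surface_agreement`: `n`,
#'   `mean_abs_rel_diff` (relative to the reference), `r_squared`,
#'   `tls_slope`, `tls_intercept`, `ccc`.
#' @export
surface_agreement <- function(recon_volumes, reference_volumes) {
  x <- as.numeric(reference_volumes); y <- as.numeric(recon_volumes)
  if (length(x) != length(y) || length(x) < 3L)
    stop("surface_agreement needs paired vectors of length >= 3")
  if (var(x) == 0 || var(y) == 0)
    stop("surface_agreement: zero variance in a volume vector")
  rel <- abs(y - x) / x
  fit <- lm(y ~ x)
  tls <- tls_fit(x, y)
  structure(list(n = length(x),
                 mean_abs_rel_diff = mean(rel),
                 r_squared = 1 - sum(fit$residuals^2) / sum((y - mean(y))^2),
                 tls_slope = tls$slope,
                 tls_intercept = tls$intercept,
                 ccc = lins_ccc(x, y)),
            class = "surface_agreement")
}

#' @export
print.surface_agreement <- function(x, ...) {
  cat(sprintf(paste0("<surface_agreement: n = %d, mean |rel diff| = %.1f%%, ",
                     "R^2 = %.3f, TLS slope = %.3f, CCC = %.3f>\n"),
              x$n, 100 * x$mean_abs_rel_diff, x$r_squared, x$tls_slope, x$ccc))
  invisible(x)
}

#' Export a terrain grid as an ESRI ASCII grid
#'
#' @param terrain a `terrain_grid`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_terrain_asc <- function(terrain, path) {
  nx <- nrow(terrain$z); ny <- ncol(terrain$z)
  hdr <- c(sprintf("ncols %d", nx), sprintf("nrows %d", ny),
           sprintf("xllcorner %.10g", terrain$x0),
           sprintf("yllcorner %.10g", terrain$y0),
           sprintf("cellsize %.10g", terrain$cell_size),
           "NODATA_value -9999")
  z <- terrain$z
  z[is.na(z)] <- -9999
  rows <- vapply(rev(seq_len(ny)), function(j)
    paste(sprintf("%.8g", z[, j]), collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_terrain_asc()]
#'
#' @param path input path.
#' @return a `terrain_grid`.
#' @export
read_terrain_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  val <- function(key) {
    for (h in hdr) if (h[1] == key) return(as.numeric(h[2]))
    stop("missing ", key, " in ", path)
  }
  nx <- as.integer(val("ncols")); ny <- as.integer(val("nrows"))
  z <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny))
    z[, ny - j + 1L] <- as.numeric(strsplit(trimws(lines[6L + j]), "\\s+")[[1]])
  z[z == -9999] <- NA_real_
  structure(list(x0 = val("xllcorner"), y0 = val("yllcorner"),
                 cell_size = val("cellsize"), z = z),
            class = "terrain_grid")
}
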