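## The three volumetric estimators: canopy height model (CHM) mean height,
## 3-D convex hull, and voxel occupancy across edge lengths.

#' Canopy height model parameters
#'
#' @param cell_size CHM grid resolution (m), default 0.01.
#' @param fill_neighborhood odd window width (cells) for inverse-distance
#'   gap filling, default 7 (a 7 x 7 neighborhood).
#' @param idw_power inverse-distance weighting exponent, default 2.
#' @return a list of class `chm_params`.
#' @export
chm_params <- function(cell_size = 0.01, fill_neighborhood = 7L, idw_power = 2) {
  stopifnot(cell_size > 0, fill_neighborhood >= 3L,
            fill_neighborhood %% 2L == 1L, idw_power > 0)
  structure(list(cell_size = cell_size,
                 fill_neighborhood = as.integer(fill_neighborhood),
                 idw_power = idw_power),
            class = "chm_params")
}

#' Compute a canopy height model and its plot-level volume
#'
#' Rasterizes the maximum height above ground per cell over the quadrat
#' frame. Empty cells are filled with the inverse-distance-weighted mean of
#' the non-empty cells inside the `fill_neighborhood` window (distances
#' between cell centers, the target cell excluded); cells with no filled
#' neighbor in the window stay empty and are excluded from the mean. The
#' plot mean canopy height is the average over non-empty cells, and the CHM
#' volume is that mean times the frame area (0.2 m^2 at the default frame).
#'
#' @param heights heights above ground (m) per point, e.g. from
#'   [points_above_surface()].
#' @param xy an `N x 2` matrix of the matching point coordinates.
#' @param frame a [quadrat_frame()].
#' @param params a [chm_params()] set.
#' @return a list of class `chm`: `grid` (matrix, NA = empty),
#'   `mean_height` (m), `volume` (m^3), `n_filled` (cells gap-filled),
#'   `empty` (TRUE when no point fell inside the frame).
#' @export
compute_chm <- function(heights, xy, frame, params = chm_params()) {
  stopifnot(inherits(frame, "quadrat_frame"))
  cs <- params$cell_size
  nx <- max(1L, round(frame$width_x / cs))
  ny <- max(1L, round(frame$width_y / cs))
  grid <- matrix(NA_real_, nx, ny)
  heights <- as.numeric(heights)
  if (length(heights)) {
    xy <- matrix(xy, ncol = 2)
    ix <- floor((xy[, 1] - frame$x0) / cs)
    iy <- floor((xy[, 2] - frame$y0) / cs)
    ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
    ix <- ix[ok]; iy <- iy[ok]; h <- heights[ok]
    if (length(h)) {
      cell <- ix + nx * iy + 1L
      o <- order(cell, -h)
      first <- o[!duplicated(cell[o])]
      grid[cell[first]] <- h[first]
    }
  }
  if (all(is.na(grid)))
    return(structure(list(grid = grid, mean_height = 0, volume = 0,
                          n_filled = 0L, empty = TRUE), class = "chm"))
  # IDW gap fill within the window
  half <- (params$fill_neighborhood - 1L) %/% 2L
  empty_cells <- which(is.na(grid), arr.ind = TRUE)
  filled <- grid
  n_filled <- 0L
  if (nrow(empty_cells)) {
    off <- expand.grid(di = -half:half, dj = -half:half)
    off <- off[!(off$di == 0 & off$dj == 0), ]
    wdist <- (off$di^2 + off$dj^2)^(params$idw_power / 2) * cs^params$idw_power
    for (r in seq_len(nrow(empty_cells))) {
      i <- empty_cells[r, 1]; j <- empty_cells[r, 2]
      ii <- i + off$di; jj <- j + off$dj
      ok <- ii >= 1 & ii <= nrow(grid) & jj >= 1 & jj <= ncol(grid)
      if (!any(ok)) next
      v <- grid[cbind(ii[ok], jj[ok])]
      have <- !is.na(v)
      if (!any(have)) next
      w <- 1 / wdist[ok][have]
      filled[i, j] <- sum(w * v[have]) / sum(w)
      n_filled <- n_filled + 1L
    }
  }
  mh <- mean(filled[!is.na(filled)])
  structure(list(grid = filled, mean_height = mh, volume = mh * frame$area,
                 n_filled = n_filled, empty = FALSE), class = "chm")
}

#' Volume of the 3-D convex hull of a point set
#'
#' The smallest convex solid enclosing the points; computed with an
#' incremental (quickhull) construction. Fewer than 4 points, or a
#' degenerate (collinear/coplanar) set, yields volume 0 with a flag.
#'
#' @param points a [point_cloud()] or `N x 3` matrix.
#' @return a list: `volume` (m^3), `degenerate` (logical), `n_vertices`
#'   (hull vertices).
#' @export
convex_hull_volume <- function(points) {
  m <- if (inherits(points, "point_cloud")) points$coords else {
    pm <- as.matrix(points)
    stopifnot(ncol(pm) == 3L)
    pm
  }
  storage.mode(m) <- "double"
  cpp_convex_hull_volume(m)
}

#' Voxel-occupancy volume
#'
#' Points are binned into cubic half-open cells of side `edge` anchored at
#' `origin` (`index = floor((coord - origin) / edge)` per axis); the volume
#' is the number of distinct occupied cells times `edge^3`. Occupancy, not
#' density: multiple points in a cell count once.
#'
#' @param points a [point_cloud()] or `N x 3` matrix.
#' @param edge voxel edge length (m), > 0.
#' @param origin grid anchor, length 3 (m). By convention the quadrat frame
#'   corner at the terrain minimum elevation; a shared origin across edge
#'   lengths makes nested-edge volumes monotone.
#' @return a list: `occupied_count`, `volume` (m^3).
#' @export
voxel_volume <- function(points, edge, origin = c(0, 0, 0)) {
  stopifnot(edge > 0, length(origin) == 3L)
  m <- if (inherits(points, "point_cloud")) points$coords else as.matrix(points)
  if (nrow(m) == 0L) return(list(occupied_count = 0L, volume = 0))
  storage.mode(m) <- "double"
  cnt <- cpp_voxel_count(m, edge, as.numeric(origin))
  list(occupied_count = as.integer(cnt), volume = cnt * edge^3)
}

#' Default voxel edge lengths: 2 to 100 mm
#'
#' @return numeric vector of edge lengths in meters.
#' @export
default_voxel_edges <- function() {
  c(0.002, 0.0025, 0.005, 0.01, 0.02, 0.025, 0.04, 0.05, 0.075, 0.1)
}

#' Voxel volumes across a sweep of edge lengths
#'
#' Applies [voxel_volume()] at each edge with a shared origin.
#'
#' @inheritParams voxel_volume
#' @param edge_lengths ascending voxel edges (m); default
#'   [default_voxel_edges()] (2-100 mm).
#' @return a data.frame with columns `edge_m`, `occupied_count`,
#'   `volume_m3`.
#' @export
voxel_size_sweep <- function(points, edge_lengths = default_voxel_edges(),
                             origin = c(0, 0, 0)) {
  stopifnot(all(edge_lengths > 0), !is.unsorted(edge_lengths))
  rows <- lapply(edge_lengths, function(e) {
    v <- voxel_volume(points, e, origin)
    data.frame(edge_m = e, occupied_count = v$occupied_count,
               volume_m3 = v$volume)
  })
  do.call(rbind, rows)
}
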