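## Simple morphological filter (SMRF) ground classification.
##
## A minimum-elevation raster is built over the plot, opened progressively
## with disk windows of radius 1..max_window_radius cells, and cells rising
## above the opened surface faster than the slope threshold allows are
## flagged as objects. Points within elevation_threshold of the interpolated
## provisional ground raster are labeled ground.

# min over disk-shaped neighborhoods, ignoring out-of-grid cells
.disk_offsets <- function(w) {
  d <- expand.grid(di = -w:w, dj = -w:w)
  d[d$di^2 + d$dj^2 <= w^2, , drop = FALSE]
}

.morph <- function(z, offsets, op) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(if (identical(op, pmin)) Inf else -Inf, nr, nc)
  for (r in seq_len(nrow(offsets))) {
    di <- offsets$di[r]; dj <- offsets$dj[r]
    src_i <- max(1, 1 - di):min(nr, nr - di)
    src_j <- max(1, 1 - dj):min(nc, nc - dj)
    out[src_i, src_j] <- op(out[src_i, src_j],
                            z[src_i + di, src_j + dj])
  }
  out
}

.opening <- function(z, w) {
  off <- .disk_offsets(w)
  .morph(.morph(z, off, pmin), off, pmax)
}

# Linear interpolation over a triangulation of scattered (x, y, z), with
# nearest-neighbor fill outside the convex hull; exact on planes.
.fill_surface <- function(x, y, z, qx, qy) {
  n <- length(x)
  out <- rep(NA_real_, length(qx))
  collinear <- n < 3 ||
    qr(cbind(x - mean(x), y - mean(y)), tol = 1e-10)$rank < 2L
  if (!collinear) {
    fit <- tryCatch(
      withCallingHandlers(
        interp::interpp(x = x, y = y, z = z, xo = qx, yo = qy,
                        linear = TRUE, duplicate = "mean"),
        # near-regular inputs trigger a benign, deterministic jitter retry
        warning = function(w) {
          if (grepl("jitter", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit)) out <- fit$z
  }
  nas <- which(is.na(out))
  if (length(nas)) {
    nn <- FNN::get.knnx(cbind(x, y), cbind(qx[nas], qy[nas]), k = 1L)$nn.index[, 1]
    out[nas] <- z[nn]
  }
  out
}

#' SMRF parameter set
#'
#' Defaults follow the field parameterization for mostly flat 0.2 m^2 plots:
#' elevation threshold 0.11 m, slope threshold 0.1, elevation scale 0.9,
#' maximum window radius 10 cells. The cell size (0.01 m) matches the canopy
#' height model grid.
#'
#' @param cell_size raster cell edge (m).
#' @param elevation_threshold maximum height above the provisional ground
#'   surface for a point to be classified as ground (m).
#' @param slope_threshold permitted elevation gain per meter of window growth
#'   (dimensionless).
#' @param elevation_scale multiplier applied to the slope-driven threshold at
#'   each window step.
#' @param max_window_radius largest opening radius, in cells (integer >= 1).
#' @return a list of class `smrf_params`.
#' @export
smrf_params <- function(cell_size = 0.01, elevation_threshold = 0.11,
                        slope_threshold = 0.1, elevation_scale = 0.9,
                        max_window_radius = 10L) {
  stopifnot(cell_size > 0, elevation_threshold > 0, slope_threshold > 0,
            elevation_scale > 0, max_window_radius >= 1)
  structure(list(cell_size = cell_size,
                 elevation_threshold = elevation_threshold,
                 slope_threshold = slope_threshold,
                 elevation_scale = elevation_scale,
                 max_window_radius = as.integer(max_window_radius)),
            class = "smrf_params")
}

#' Classify ground vs vegetation with the simple morphological filter
#'
#' Rasterizes the minimum elevation per cell, inpaints empty cells from their
#' nearest filled neighbor, applies progressive morphological opening with
#' disk windows of radius `1..max_window_radius` cells (flagging cells whose
#' elevation drops by more than
#' `elevation_scale * slope_threshold * (radius * cell_size)` under the
#' opening at that radius), interpolates the unflagged minimum surface into a
#' provisional ground raster, and labels points whose height above that
#' raster is at most `elevation_threshold` as ground.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param params an [smrf_params()] set.
#' @param frame optional [quadrat_frame()] fixing the raster extent;
#'   defaults to the cloud's xy bounding box.
#' @return integer labels per point: 1 = ground, 2 = vegetation.
#' @export
smrf_classify <- function(cloud, params = smrf_params(), frame = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$coords)
  if (n == 0L) stop("smrf_classify needs a non-empty cloud")
  cs <- params$cell_size
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]; z <- cloud$coords[, 3]
  if (is.null(frame)) {
    x0 <- min(x); y0 <- min(y)
    nx <- max(1L, ceiling((max(x) - x0) / cs + 1e-9))
    ny <- max(1L, ceiling((max(y) - y0) / cs + 1e-9))
  } else {
    x0 <- frame$x0; y0 <- frame$y0
    nx <- max(1L, round(frame$width_x / cs))
    ny <- max(1L, round(frame$width_y / cs))
  }
  if (nx < 2L || ny < 2L)
    stop("cloud extent is degenerate: needs >= 2 cells in each axis at cell_size = ", cs)
  ix <- pmin(pmax(floor((x - x0) / cs), 0), nx - 1L)
  iy <- pmin(pmax(floor((y - y0) / cs), 0), ny - 1L)
  cell <- ix + nx * iy + 1L

  zmin <- matrix(NA_real_, nx, ny)
  o <- order(cell, z)
  first <- o[!duplicated(cell[o])]
  zmin[cell[first]] <- z[first]

  # inpaint empty cells from the nearest filled cell
  cx <- x0 + (seq_len(nx) - 0.5) * cs
  cy <- y0 + (seq_len(ny) - 0.5) * cs
  centers <- cbind(rep(cx, ny), rep(cy, each = nx))
  filled <- which(!is.na(zmin))
  if (length(filled) < length(zmin)) {
    empty <- which(is.na(zmin))
    nn <- FNN::get.knnx(centers[filled, , drop = FALSE],
                        centers[empty, , drop = FALSE], k = 1L)$nn.index[, 1]
    zmin[empty] <- zmin[filled][nn]
  }

  # progressive opening
  zlast <- zmin
  object <- matrix(FALSE, nx, ny)
  for (w in seq_len(params$max_window_radius)) {
    opened <- .opening(zlast, w)
    thr <- params$elevation_scale * params$slope_threshold * (w * cs)
    object <- object | (zlast - opened > thr)
    zlast <- opened
  }

  # provisional ground raster: unflagged minimum-surface cells, object cells
  # filled from the nearest unflagged cell (the raster only gates the 11 cm
  # elevation test, so nearest-neighbor inpainting is ample)
  gcell <- which(!object)
  if (length(gcell) == 0L) gcell <- seq_along(zmin)  # everything flagged: fall back
  gsurf <- matrix(NA_real_, nx, ny)
  gsurf[gcell] <- zmin[gcell]
  ocell <- which(is.na(gsurf))
  if (length(ocell)) {
    nn <- FNN::get.knnx(centers[gcell, , drop = FALSE],
                        centers[ocell, , drop = FALSE], k = 1L)$nn.index[, 1]
    gsurf[ocell] <- zmin[gcell][nn]
  }

  height <- z - gsurf[cbind(ix + 1L, iy + 1L)]
  ifelse(height <= params$elevation_threshold, 1L, 2L)
}
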