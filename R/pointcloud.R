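#' Construct a point cloud
#'
#' The package's basic container: an `N x 3` coordinate matrix in meters
#' (z-up), with optional per-point RGB (0-255) and class labels
#' (0 = unlabeled, 1 = ground, 2 = vegetation).
#'
#' @param coords numeric matrix with 3 columns (x, y, z) in meters; a vector
#'   of length 3 is accepted for a single point.
#' @param rgb optional `N x 3` matrix of colors in `[0, 255]`.
#' @param labels optional integer vector of length `N` with values in
#'   `{0, 1, 2}`.
#' @return an object of class `point_cloud`.
#' @export
point_cloud <- function(coords, rgb = NULL, labels = NULL) {
  if (is.null(coords)) coords <- matrix(numeric(0), ncol = 3)
  if (is.vector(coords) && length(coords) == 3L) coords <- matrix(coords, ncol = 3)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (n > 0 && !all(is.finite(coords))) stop("all coordinates must be finite")
  colnames(coords) <- c("x", "y", "z")
  if (!is.null(rgb)) {
    rgb <- as.matrix(rgb)
    if (nrow(rgb) != n || ncol(rgb) != 3L) stop("rgb must be an N x 3 matrix")
    if (n > 0 && (min(rgb) < 0 || max(rgb) > 255)) stop("rgb values must lie in [0, 255]")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("labels must have length N = ", n)
    if (n > 0 && !all(labels %in% 0:2)) stop("labels must be in {0, 1, 2}")
  }
  structure(list(coords = coords, rgb = rgb, labels = labels),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- nrow(x$coords)
  cat(sprintf("<point_cloud: %d points%s%s>\n", n,
              if (!is.null(x$rgb)) ", rgb" else "",
              if (!is.null(x$labels)) sprintf(", labels (%d ground, %d vegetation)",
                                              sum(x$labels == 1L), sum(x$labels == 2L))
              else ""))
  invisible(x)
}

#' @export
length.point_cloud <- function(x) nrow(x$coords)

#' Subset a point cloud by point index
#'
#' Keeps rgb and labels aligned with the retained coordinates.
#'
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index over points.
#' @return a `point_cloud` with the selected points, order preserved.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$coords[idx, , drop = FALSE],
              rgb = if (!is.null(cloud$rgb)) cloud$rgb[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx])
}

#' Define a quadrat sampling frame
#'
#' The inner sampling window of the field frame: a 0.4 m x 0.5 m (0.2 m^2)
#' axis-aligned rectangle. Plot-local membership uses half-open intervals
#' `[x0, x0 + width_x) x [y0, y0 + width_y)` so that shared boundaries are
#' never double counted across adjacent cells or frames.
#'
#' @param x0,y0 lower-left inner corner (m). Default `(0, 0)`.
#' @param width_x,width_y frame extents (m); defaults 0.4 and 0.5.
#' @return an object of class `quadrat_frame` with fields `x0`, `y0`,
#'   `width_x`, `width_y`, `area`.
#' @export
quadrat_frame <- function(x0 = 0, y0 = 0, width_x = 0.4, width_y = 0.5) {
  stopifnot(width_x > 0, width_y > 0, is.finite(x0), is.finite(y0))
  structure(list(x0 = x0, y0 = y0, width_x = width_x, width_y = width_y,
                 area = width_x * width_y),
            class = "quadrat_frame")
}

#' Clip a point cloud to a quadrat frame
#'
#' Retains exactly the points whose (x, y) fall inside the half-open frame
#' rectangle; z is unrestricted and point order is preserved. Idempotent.
#'
#' @param cloud a [point_cloud()].
#' @param frame a [quadrat_frame()].
#' @return the clipped `point_cloud` (possibly empty).
#' @export
clip_to_frame <- function(cloud, frame) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(frame, "quadrat_frame"))
  x <- cloud$coords[, 1]; y <- cloud$coords[, 2]
  keep <- x >= frame$x0 & x < frame$x0 + frame$width_x &
          y >= frame$y0 & y < frame$y0 + frame$width_y
  subset_cloud(cloud, keep)
}
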