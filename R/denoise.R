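#' Per-point mean distance to the k nearest neighbors
#'
#' For each point, the mean Euclidean distance to its `k` nearest other
#' points (self excluded). Exact; computed with a uniform-grid spatial index.
#'
#' @param cloud a [point_cloud()].
#' @param k number of neighbors (>= 1).
#' @return numeric vector of length N, meters.
#' @export
knn_mean_distance <- function(cloud, k = 10L) {
  stopifnot(inherits(cloud, "point_cloud"), k >= 1L)
  n <- nrow(cloud$coords)
  if (n <= k)
    stop("knn_mean_distance needs at least k + 1 = ", k + 1L, " points, got ", n)
  cpp_knn_mean_dist(cloud$coords, as.integer(k))
}

#' Statistical outlier removal
#'
#' Implements the classic k-nearest-neighbor statistical outlier filter:
#' a point is removed when its mean distance to its `k` nearest neighbors
#' exceeds a threshold. In `"sigma"` mode (default) the threshold is
#' `mu + std_multiplier * sigma`, where `mu` and `sigma` are the mean and
#' standard deviation of the per-point mean distances over the whole cloud.
#' In `"absolute"` mode the threshold is `abs_threshold` meters.
#'
#' Applied once (no iteration). Output points keep their input order.
#'
#' @param cloud a [point_cloud()].
#' @param k neighbors used for the mean distance (default 10).
#' @param std_multiplier sigma multiplier (default 1), `"sigma"` mode.
#' @param mode `"sigma"` or `"absolute"`.
#' @param abs_threshold absolute distance threshold (m), `"absolute"` mode.
#' @return a list with `cloud` (the filtered [point_cloud()]), `removed`
#'   (count), and `threshold` (the distance cut actually applied, m).
#' @export
statistical_outlier_filter <- function(cloud, k = 10L, std_multiplier = 1,
                                       mode = c("sigma", "absolute"),
                                       abs_threshold = NULL) {
  mode <- match.arg(mode)
  stopifnot(std_multiplier > 0)
  d <- knn_mean_distance(cloud, k)
  thr <- if (mode == "sigma") mean(d) + std_multiplier * sd(d)
         else {
           if (is.null(abs_threshold) || abs_threshold <= 0)
             stop("absolute mode needs a positive abs_threshold (m)")
           abs_threshold
         }
  keep <- d <= thr
  # never drop below k + 1 points (the filter must stay re-runnable)
  if (sum(keep) < k + 1L) keep <- rank(d, ties.method = "first") <= k + 1L
  list(cloud = subset_cloud(cloud, keep), removed = sum(!keep), threshold = thr)
}
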