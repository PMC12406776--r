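check_points <- function(points) {
  points <- as_tibble(points)
  if (!all(c("x", "y") %in% names(points)))
    abort("`points` must have columns `x` and `y`")
  if (nrow(points) < 1L || any(!is.finite(points$x)) || any(!is.finite(points$y)))
    abort("`points` must contain at least one finite (x, y) pair")
  points
}

#' Nearest-neighbor distances of a planar point set
#'
#' For each point (e.g. an astrocyte soma position), the Euclidean
#' distance to its closest other point — the classic measure of how
#' evenly cells tile a territory.
#'
#' @param points A data frame with numeric columns `x` and `y` (pixel or
#'   micrometre coordinates; distances inherit the unit).
#' @return A tibble with columns `point` (row index) and `nn_distance`.
#' @examples
#' nearest_neighbor_distances(data.frame(x = c(0, 1, 3), y = 0))
#' @export
nearest_neighbor_distances <- function(points) {
  points <- check_points(points)
  if (nrow(points) < 2L) abort("need at least 2 points")
  dm <- as.matrix(dist(cbind(points$x, points$y)))
  diag(dm) <- Inf
  tibble(point = seq_len(nrow(points)), nn_distance = unname(apply(dm, 1L, min)))
}

#' Mean distance to the k nearest neighbors
#'
#' For each point, the mean Euclidean distance to its `k` closest other
#' points (default `k = 9`), a smoother tiling statistic than the single
#' nearest neighbor.  No edge correction is applied: points near the
#' field border are treated like interior points.
#'
#' @param points A data frame with numeric columns `x` and `y`.
#' @param k Number of neighbors to average over; must be smaller than the
#'   number of points.
#' @return A tibble with columns `point` and `k_mean_distance`.
#' @export
k_neighbor_mean_distances <- function(points, k = 9L) {
  points <- check_points(points)
  n <- nrow(points)
  if (k < 1L || k >= n) abort("`k` must satisfy 1 <= k < number of points")
  dm <- as.matrix(dist(cbind(points$x, points$y)))
  diag(dm) <- Inf
  km <- apply(dm, 1L, function(d) mean(sort(d)[seq_len(k)]))
  tibble(point = seq_len(n), k_mean_distance = unname(km))
}

#' Combined neighbor statistics
#'
#' Convenience wrapper returning both the nearest-neighbor distance and
#' the mean distance to `k` neighbors per point.
#'
#' @inheritParams k_neighbor_mean_distances
#' @return A tibble of class `astro_neighbors` with columns `point`,
#'   `nn_distance`, `k_mean_distance`; attribute `k`.
#' @export
neighbor_stats <- function(points, k = 9L) {
  out <- left_join(nearest_neighbor_distances(points),
                   k_neighbor_mean_distances(points, k), by = "point")
  attr(out, "k") <- as.integer(k)
  class(out) <- c("astro_neighbors", class(out))
  out
}

#' Cluster areas of a thresholded, blurred projection
#'
#' Maximum-projects a (possibly multi-page) image, applies an isotropic
#' Gaussian blur, binarises at `threshold`, and records the pixel area of
#' every 8-connected component strictly larger than `min_area` (the
#' conventional 500-px floor for astrocyte clusters at low
#' magnification).
#'
#' @param img An intensity matrix or a list of matrices (pages) to
#'   max-project.
#' @param blur_sigma Gaussian blur radius in pixels (default 1; 0
#'   disables blurring).
#' @param threshold Binarisation threshold (required; pixels strictly
#'   above it are foreground).
#' @param min_area Only components with area strictly above this many
#'   pixels are reported (default 500).
#' @return A tibble with columns `cluster_id` and `area_px`, sorted by
#'   decreasing area.
#' @export
cluster_areas <- function(img, blur_sigma = 1, threshold, min_area = 500L) {
  if (is.list(img)) {
    img <- Reduce(pmax, lapply(img, check_image))
  } else img <- check_image(img)
  stopifnot(blur_sigma >= 0, min_area >= 1)
  if (blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(img, sigma = blur_sigma))
  lab <- label_components(img > threshold, 8L)
  areas <- if (max(lab) > 0L) tabulate(lab[lab > 0L], max(lab)) else integer(0)
  areas <- sort(areas[areas > min_area], decreasing = TRUE)
  tibble(cluster_id = seq_along(areas), area_px = as.integer(areas))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum absolute difference between the empirical cumulative
#' distribution functions of two samples, computed by enumerating all
#' step points.  Only the statistic `D` is returned (no p-value).
#'
#' @param a,b Non-empty numeric samples.
#' @return A single number in `[0, 1]`.
#' @examples
#' ks_statistic(c(0, 1), c(2, 3))   # disjoint supports: 1
#' @export
ks_statistic <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) abort("samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("samples must be finite")
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}
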