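# Animal extraction from the raw capture: axis-range crop, RANSAC ground
# plane removal ("planar template matching" read as plane consensus plus a
# total-least-squares refit), and statistical outlier removal.

#' Passthrough filter (axis-aligned crop)
#'
#' Keeps exactly the points whose coordinate on `axis` lies in `[lo, hi]`;
#' point order is preserved.
#'
#' @param cloud a [point_cloud()].
#' @param axis one of `"a"`, `"b"`, `"c"`.
#' @param lo,hi range bounds in metres (`lo <= hi`); infinite bounds allowed.
#' @export
passthrough_filter <- function(cloud, axis, lo, hi) {
  stopifnot(is_point_cloud(cloud))
  if (!is.numeric(lo) || !is.numeric(hi) || is.na(lo) || is.na(hi)) {
    stop("lo and hi must be numeric")
  }
  if (lo > hi) stop("lo must not exceed hi")
  v <- cloud$points[, axis_col(axis)]
  subset_cloud(cloud, v >= lo & v <= hi)
}

#' Remove the dominant ground plane
#'
#' Fits the dominant plane by randomised consensus: `iterations` random
#' 3-point samples, inliers counted within `distance_threshold`, best sample
#' refit by total least squares on its inliers. The plane normal is oriented
#' so the centroid of the remaining (animal) points lies on its positive
#' side.
#'
#' @param cloud a [point_cloud()] with at least 3 non-collinear points.
#' @param distance_threshold inlier distance in metres.
#' @param iterations number of RANSAC draws.
#' @param seed RNG seed for reproducible draws (`NULL` = current stream).
#' @return list with elements `animal` (cloud minus plane inliers) and
#'   `plane` (a [ground_plane()]).
#' @export
remove_ground <- function(cloud, distance_threshold = 0.01,
                          iterations = 200, seed = NULL) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to fit a plane")
  with_seed(seed, {
    best_count <- -1L
    best_inl <- NULL
    for (it in seq_len(iterations)) {
      idx <- sample.int(n, 3L)
      p1 <- pts[idx[1L], ]; p2 <- pts[idx[2L], ]; p3 <- pts[idx[3L], ]
      nv <- cross3(p2 - p1, p3 - p1)
      nn <- sqrt(sum(nv^2))
      if (nn < 1e-12) next
      nv <- nv / nn
      d <- abs(drop(pts %*% nv) - sum(nv * p1))
      cnt <- sum(d < distance_threshold)
      if (cnt > best_count) {
        best_count <- cnt
        best_inl <- d < distance_threshold
      }
    }
    if (is.null(best_inl)) stop("plane fit failed: degenerate (collinear) cloud")
    # refit on consensus set, then re-classify
    plane <- fit_plane_lsq(pts[best_inl, , drop = FALSE])
    d <- plane_distance(plane, pts)
    inl <- abs(d) < distance_threshold
    if (all(inl)) {
      return(list(animal = subset_cloud(cloud, inl & FALSE), plane = plane))
    }
    ctr <- colMeans(pts[!inl, , drop = FALSE])
    if (sum(plane$normal * ctr) + plane$offset < 0) {
      plane <- ground_plane(-plane$normal, -plane$offset)
    }
    list(animal = subset_cloud(cloud, !inl), plane = plane)
  })
}

#' Statistical outlier removal
#'
#' For each point, the mean distance to its `k` nearest neighbours is
#' computed; points whose mean distance exceeds the global mean plus
#' `alpha` standard deviations of those per-point means are removed. A cloud
#' with zero distance variance (perfect grid) keeps all points.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k neighbour count.
#' @param alpha standard-deviation multiplier.
#' @export
statistical_outlier_filter <- function(cloud, k = 20, alpha = 1.0) {
  stopifnot(is_point_cloud(cloud))
  if (k <= 0) stop("k must be positive")
  n <- n_points(cloud)
  if (n <= k) stop("cloud must have more than k points")
  md <- cpp_knn_mean_dist(cloud$points, as.integer(k))
  s <- sd(md)
  if (!is.finite(s) || s == 0) return(cloud)
  subset_cloud(cloud, md <= mean(md) + alpha * s)
}
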