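# Occlusion-hole repair: slice the cloud into axis-aligned slabs, thin each
# slab to interval representatives, project onto the transverse plane, fit a
# uniform cubic B-spline, and restore fitted points into flagged gaps at the
# slab midline.

#' Slice a cloud into axis-aligned slabs
#'
#' The slab thickness `eps` defaults to the minimum distance from the cloud
#' centroid to any other point; slab count is
#' `M_S = floor((a_max - a_min) / eps)` and slab `i` covers
#' `[a_min + (i-1) eps, a_min + i eps]`. Points beyond the last full slab
#' (including the `a_max` edge) are clamped into slab `M_S`. Note the
#' centroid-distance default is of the order of the body's smallest
#' half-axis for a surface cloud; [repair_cloud()] overrides it with a
#' spacing-based slab width.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param axis primary (slicing) axis, default `"a"`.
#' @param eps slab thickness in metres; `NULL` = centroid-distance default.
#' @return an object of class `slice_set`: fields `eps`, `a_min`, `a_max`,
#'   `M_S`, `slab_index` (per point) and `slabs` (per-slab point indices).
#' @export
slice_cloud <- function(cloud, axis = "a", eps = NULL) {
  stopifnot(is_point_cloud(cloud))
  if (n_points(cloud) == 0L) stop("cloud is empty")
  pts <- cloud$points
  av <- pts[, axis_col(axis)]
  a_min <- min(av); a_max <- max(av)
  if (is.null(eps)) {
    ctr <- colMeans(pts)
    dd <- sqrt(rowSums(sweep(pts, 2L, ctr)^2))
    dd <- dd[dd > 0]
    if (!length(dd)) stop("cannot derive a slab thickness: all points coincide")
    eps <- min(dd)
  }
  if (eps <= 0) stop("slab thickness must be positive")
  M_S <- max(1L, as.integer(floor((a_max - a_min) / eps)))
  idx <- pmin(as.integer(floor((av - a_min) / eps)) + 1L, M_S)
  structure(list(eps = eps, a_min = a_min, a_max = a_max, M_S = M_S,
                 axis = axis, slab_index = idx,
                 slabs = split(seq_along(av), factor(idx, levels = 1:M_S))),
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  cat(sprintf("<slice_set: %d slabs of %.4g m over [%.4g, %.4g] on axis %s>\n",
              x$M_S, x$eps, x$a_min, x$a_max, x$axis))
  invisible(x)
}

#' Interval representatives of a slab
#'
#' Partitions a slab's points into intervals of width `eps` along the
#' secondary axis (`M_i = floor((v_max - v_min)/eps)`, edge points clamped
#' into the last interval) and returns the centroid of each non-empty
#' interval; empty intervals yield no representative.
#'
#' @param points matrix of the slab's points (2 or 3 columns).
#' @param axis secondary-axis column (name `"a"`, `"b"`, `"c"` for 3-column
#'   input, or a column number).
#' @param eps interval width in metres.
#' @return list with `representatives` (one row per non-empty interval),
#'   `counts` (members per representative), `interval` (interval index of
#'   each representative) and `M` (interval count).
#' @export
interval_representatives <- function(points, axis = "b", eps) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) stop("slab is empty")
  colv <- if (is.character(axis) && ncol(pts) == 2L) {
    match(axis, c("b", "c"))
  } else axis_col(axis)
  v <- pts[, colv]
  v_min <- min(v); v_max <- max(v)
  M <- max(1L, as.integer(floor((v_max - v_min) / eps)))
  l <- pmin(as.integer(floor((v - v_min) / eps)) + 1L, M)
  f <- factor(l, levels = sort(unique(l)))
  reps <- rowsum(pts, f, reorder = TRUE)
  counts <- as.vector(table(f))
  reps <- reps / counts
  list(representatives = unname(reps), counts = counts,
       interval = as.integer(levels(f)), M = M)
}

# Algebraic (Kasa) circle fit; returns the centre. Used as the angular
# origin of ring slabs: the point centroid of a partial arc is badly offset
# from the arc's own centre, which would misjudge gap widths.
circle_center <- function(pts2d) {
  A <- cbind(2 * pts2d, 1)
  rhs <- rowSums(pts2d^2)
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) return(colMeans(pts2d))
  ctr <- sol[1:2]
  # reject wildly extrapolated centres (nearly collinear data)
  if (sqrt(sum((ctr - colMeans(pts2d))^2)) >
      4 * max(apply(pts2d, 2L, function(v) diff(range(v))))) {
    return(colMeans(pts2d))
  }
  ctr
}

# Thin a closed slab (2D ring in the projection plane) into per-angular-bin
# centroids about the fitted ring centre. The printed interval
# representatives average the two arcs a secondary-axis interval cuts from
# a ring, so closed slices are binned in the ring's own angular coordinate
# instead.
angular_representatives <- function(pts2d, eps = NULL, n_bins = NULL) {
  ctr <- circle_center(pts2d)
  rel <- sweep(pts2d, 2L, ctr)
  r_med <- median(sqrt(rowSums(rel^2)))
  if (is.null(n_bins)) {
    n_bins <- max(12L, as.integer(floor(2 * pi * r_med / eps)))
  }
  theta <- atan2(rel[, 2L], rel[, 1L]) %% (2 * pi)
  bin <- pmin(as.integer(floor(theta / (2 * pi / n_bins))) + 1L, n_bins)
  f <- factor(bin, levels = sort(unique(bin)))
  reps <- rowsum(pts2d, f, reorder = TRUE) / as.vector(table(f))
  ang <- rowsum(theta, f, reorder = TRUE) / as.vector(table(f))
  ord <- order(ang)
  list(representatives = unname(reps[ord, , drop = FALSE]),
       angles = as.vector(ang)[ord], center = ctr, n_bins = n_bins)
}

# Cyclic gap detection on sorted angles: intervals whose spacing exceeds
# gap_factor x median spacing. Returns a list of c(lo, hi, i, j) where
# (lo, hi) is the angle interval (hi may exceed 2*pi for the wrap-around
# gap), shrunk by half the median spacing at each end, and i, j index the
# representatives rimming the gap.
angular_gaps <- function(angles, gap_factor) {
  n <- length(angles)
  if (n < 4L) return(list())
  d <- diff(c(angles, angles[1L] + 2 * pi))
  med <- median(d)
  out <- list()
  for (i in which(d > gap_factor * med)) {
    lo <- angles[i] + med / 2
    hi <- angles[i] + d[i] - med / 2
    if (hi > lo) out[[length(out) + 1L]] <- c(lo, hi, i, (i %% n) + 1L)
  }
  out
}

in_angular_gap <- function(theta, gaps, radius = NULL) {
  hit <- rep(FALSE, length(theta))
  for (g in gaps) {
    inside <- ((theta - g[1L]) %% (2 * pi)) <= (g[2L] - g[1L])
    if (!is.null(radius) && length(g) >= 6L) {
      inside <- inside & radius >= g[5L] & radius <= g[6L]
    }
    hit <- hit | inside
  }
  hit
}

# Occlusion holes interrupt a smooth ring, so the representatives rimming a
# genuine hole sit at similar radii; a large rim jump marks a structural
# boundary (e.g. torso against leg), which must not be bridged. Fillable
# gaps get a radial band [g[5], g[6]] that restored samples are clipped to.
qualify_gaps <- function(gaps, reps, center, r_med, bin_arc) {
  keep <- list()
  rr <- sqrt(rowSums(sweep(reps, 2L, center)^2))
  for (g in gaps) {
    r1 <- rr[g[3L]]; r2 <- rr[g[4L]]
    if (abs(r1 - r2) > max(0.35 * r_med, 3 * bin_arc)) next
    marg <- max(0.1 * r_med, 2 * bin_arc)
    keep[[length(keep) + 1L]] <-
      c(g[1:4], min(r1, r2) - marg, max(r1, r2) + marg)
  }
  keep
}

#' Restore fitted curve points into a slab
#'
#' Samples the fitted projection-plane curve uniformly in parameter,
#' optionally keeps only samples inside the detected gap intervals, and
#' lifts them back to 3D with the slab-midline coordinate on the primary
#' axis.
#'
#' @param curve a [bspline_curve()] fitted in the `(b, c)` projection plane.
#' @param a_value primary-axis coordinate assigned to every restored point
#'   (the slab midline `a_min + (i - 1/2) eps`).
#' @param gaps list of angular intervals (from gap detection) to fill;
#'   `NULL` keeps every sample.
#' @param center ring centre used for the angular test (required with
#'   `gaps`).
#' @param n_samples number of curve samples.
#' @param axis primary axis the slabs were cut along.
#' @return a [point_cloud()] of restored points labelled `"repaired"`.
#' @export
repair_slice <- function(curve, a_value, gaps = NULL, center = NULL,
                         n_samples = 200, axis = "a") {
  ts <- if (curve$closed) {
    seq(0, 1, length.out = n_samples + 1L)[-(n_samples + 1L)]
  } else seq(0, 1, length.out = n_samples)
  C <- eval_curve(curve, ts)
  if (!is.null(gaps) && length(gaps)) {
    stopifnot(!is.null(center))
    rel1 <- C[, 1L] - center[1L]
    rel2 <- C[, 2L] - center[2L]
    theta <- atan2(rel2, rel1) %% (2 * pi)
    C <- C[in_angular_gap(theta, gaps, sqrt(rel1^2 + rel2^2)), ,
           drop = FALSE]
  }
  ac <- axis_col(axis)
  pts <- matrix(0, nrow(C), 3L)
  pts[, ac] <- a_value
  pts[, setdiff(1:3, ac)] <- C
  point_cloud(pts, labels = rep("repaired", nrow(C)))
}

#' Repair configuration
#'
#' @param slab_width slab thickness in metres; `NULL` = 4x the median
#'   nearest-neighbour spacing (the Eq-9 centroid-distance default is far
#'   too coarse for surface clouds; see the methods vignette).
#' @param interval_width representative-interval (bin) width in metres;
#'   `NULL` = 1.5x the median spacing. Finer than the slab width so that
#'   narrow occlusion bands still register as gaps.
#' @param n_control control points per slab fit.
#' @param iterations parameter-correction rounds per fit.
#' @param gap_factor a spacing exceeding `gap_factor` times the median
#'   flags a gap.
#' @param max_gap angular gaps wider than this (radians) are treated as the
#'   open boundary of a partial (e.g. single-side) capture rather than an
#'   occlusion hole: the slab is then fitted as an open arc and only
#'   interior gaps are filled, so the curve never extrapolates across the
#'   unseen side.
#' @param min_points slabs with fewer points are skipped.
#' @param closed treat slabs as closed cross-section rings (angular
#'   ordering); `FALSE` = open profiles ordered along the secondary axis.
#' @param axis primary (slicing) axis.
#' @param samples_per_slab curve samples per repaired slab.
#' @param lambda smoothing weight of the slab fits (see [fit_curve()]);
#'   stronger than the fitting default because the bridge across a hole
#'   has no data support.
#' @export
repair_config <- function(slab_width = NULL, interval_width = NULL,
                          n_control = 24, iterations = 10,
                          gap_factor = 3.0, max_gap = 2.0, min_points = 30,
                          closed = TRUE, axis = "a",
                          samples_per_slab = 240, lambda = 1e-2) {
  list(slab_width = slab_width, interval_width = interval_width,
       n_control = n_control,
       iterations = iterations, gap_factor = gap_factor, max_gap = max_gap,
       min_points = min_points, closed = closed, axis = axis,
       samples_per_slab = samples_per_slab, lambda = lambda)
}

# median nearest-neighbour spacing, on a subsample for large clouds
median_spacing <- function(pts, cap = 2000L) {
  n <- nrow(pts)
  sub <- if (n > cap) pts[round(seq(1L, n, length.out = cap)), , drop = FALSE]
  else pts
  median(cpp_knn_mean_dist(sub, 1L))
}

#' Repair occlusion holes in a registered cloud
#'
#' Slices the cloud along the primary axis, thins each slab to
#' representatives, detects gaps (spacing between consecutive
#' representatives exceeding `gap_factor` times the median spacing), fits a
#' uniform cubic B-spline to the representatives of flagged slabs, and
#' appends curve samples inside the gaps at the slab midline. Original
#' points are never moved or deleted; restored points carry the label
#' `"repaired"`.
#'
#' @param cloud a preprocessed, registered [point_cloud()].
#' @param config a [repair_config()].
#' @return the input cloud with repaired points appended.
#' @export
repair_cloud <- function(cloud, config = repair_config()) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  s <- median_spacing(pts)
  w <- config$slab_width %||% (4 * s)
  bin_w <- config$interval_width %||% (1.5 * s)
  ss <- slice_cloud(cloud, axis = config$axis, eps = w)
  ac <- axis_col(config$axis)
  sec <- setdiff(1:3, ac)
  added <- list()
  for (i in seq_len(ss$M_S)) {
    idx <- ss$slabs[[i]]
    if (length(idx) < config$min_points) next
    p2 <- pts[idx, sec, drop = FALSE]
    a_mid <- ss$a_min + (i - 0.5) * ss$eps
    if (config$closed) {
      ar <- angular_representatives(p2, eps = bin_w)
      gaps <- angular_gaps(ar$angles, config$gap_factor)
      if (!length(gaps)) next
      if (nrow(ar$representatives) < 8L) next
      widths <- vapply(gaps, function(g) g[2L] - g[1L], 0)
      boundary <- widths > config$max_gap
      reps <- ar$representatives
      r_med <- median(sqrt(rowSums(sweep(reps, 2L, ar$center)^2)))
      fit_closed <- !any(boundary)
      if (fit_closed) {
        # parameterise by the normalised polar angle: the gap keeps its
        # true parameter share, so bridge controls stay evenly spaced
        t_par <- ar$angles / (2 * pi)
      } else {
        # open arc: start the ordering just after the widest boundary gap
        # and fill interior gaps only
        bi <- which.max(widths)
        cut <- gaps[[bi]][2L] %% (2 * pi)
        rot <- (ar$angles - cut) %% (2 * pi)
        ord <- order(rot)
        # gap rim indices must follow the reordering
        inv <- integer(length(ord)); inv[ord] <- seq_along(ord)
        gaps <- lapply(gaps, function(g) c(g[1:2], inv[g[3L]], inv[g[4L]]))
        reps <- reps[ord, , drop = FALSE]
        rot <- rot[ord]
        t_par <- (rot - rot[1L]) / max(rot[length(rot)] - rot[1L], 1e-9)
        gaps <- gaps[!boundary]
      }
      gaps <- qualify_gaps(gaps, reps, ar$center, r_med, bin_w)
      if (!length(gaps)) next
      nc <- min(config$n_control, nrow(reps))
      curve <- suppressWarnings(
        fit_curve(reps, n_control = nc,
                  iterations = config$iterations, closed = fit_closed,
                  lambda = config$lambda, params = t_par,
                  penalty_order = 3L))
      added[[length(added) + 1L]] <-
        repair_slice(curve, a_mid, gaps = gaps, center = ar$center,
                     n_samples = config$samples_per_slab,
                     axis = config$axis)
    } else {
      ir <- interval_representatives(p2, axis = 1L, eps = bin_w)
      reps <- ir$representatives
      reps <- reps[order(reps[, 1L]), , drop = FALSE]
      if (nrow(reps) < 8L) next
      sp <- diff(reps[, 1L])
      med <- median(sp)
      gi <- which(sp > config$gap_factor * med)
      if (!length(gi)) next
      curve <- suppressWarnings(
        fit_curve(reps, n_control = min(config$n_control, nrow(reps)),
                  iterations = config$iterations, closed = FALSE,
                  lambda = config$lambda))
      ts <- seq(0, 1, length.out = config$samples_per_slab)
      C <- eval_curve(curve, ts)
      keep <- rep(FALSE, nrow(C))
      for (g in gi) {
        keep <- keep | (C[, 1L] > reps[g, 1L] + med / 2 &
                          C[, 1L] < reps[g + 1L, 1L] - med / 2)
      }
      if (!any(keep)) next
      P3 <- matrix(0, sum(keep), 3L)
      P3[, ac] <- a_mid
      P3[, sec] <- C[keep, , drop = FALSE]
      added[[length(added) + 1L]] <-
        point_cloud(P3, labels = rep("repaired", sum(keep)))
    }
  }
  if (!length(added)) return(cloud)
  base <- cloud
  if (is.null(base$labels)) {
    base$labels <- rep("original", n_points(base))
  }
  do.call(bind_clouds, c(list(base), added))
}
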