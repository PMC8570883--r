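# Pose normalisation, symmetry-plane estimation and half-body mirroring.

#' Normalise the pose of an animal cloud
#'
#' Rotates the cloud so the ground normal points along +b and the first
#' principal axis of the top-view projection along +a, disambiguating the
#' head direction so the tallest back point (withers) lies in the +a half.
#' The cloud is then translated so the ground plane becomes `b = 0` and the
#' top-view centroid sits at `a = c = 0`.
#'
#' @param cloud a non-degenerate [point_cloud()] of the animal.
#' @param ground the fitted [ground_plane()].
#' @return list with `cloud` (normalised), `transform` (the applied
#'   `rigid_transform`) and `ground` (the plane in the new frame,
#'   `b = 0`).
#' @export
normalize_pose <- function(cloud, ground) {
  stopifnot(is_point_cloud(cloud), inherits(ground, "ground_plane"))
  R1 <- rotation_between(ground$normal, c(0, 1, 0))
  pts <- cloud$points %*% t(R1)
  # longitudinal direction from the top-view (a, c) principal axis
  tv <- pts[, c(1L, 3L)]
  pc <- prcomp(tv, center = TRUE, scale. = FALSE)
  if (pc$sdev[1L] < 1.05 * pc$sdev[2L]) {
    stop("degenerate principal axes: top-view projection is isotropic")
  }
  # a rotation by psi about +b maps the top-view angle phi to phi - psi,
  # so aligning the principal axis (angle ang) with +a needs psi = ang
  ang <- atan2(pc$rotation[2L, 1L], pc$rotation[1L, 1L])
  R2 <- rotation_about_axis("b", ang)
  R <- R2 %*% R1
  pts <- cloud$points %*% t(R)
  # head-direction disambiguation: withers (tallest back point) forward
  amid <- (max(pts[, 1L]) + min(pts[, 1L])) / 2
  qb <- quantile(pts[, 2L], 0.98)
  tall <- pts[pts[, 2L] >= qb, 1L]
  if (mean(tall) < amid) {
    R <- rotation_about_axis("b", pi) %*% R
    pts <- cloud$points %*% t(R)
  }
  # translation: ground -> b = 0, top-view centroid -> a = c = 0
  n_r <- drop(R %*% ground$normal)           # == (0, 1, 0)
  p <- c(-mean(pts[, 1L]), ground$offset, -mean(pts[, 3L]))
  tf <- rigid_transform(R, p)
  list(cloud = apply_transform(tf, cloud),
       transform = tf,
       ground = ground_plane(n_r, 0))
}

#' Fit the symmetry model of a normalised cloud
#'
#' Collects the tallest point of each slab between the key points (tail
#' P5 to shoulder P4), removes outliers from that ridge range with the
#' statistical filter, fits the top-view line `c = mu0 + mu1 a` by least
#' squares, and builds the symmetry-plane normal `phi_p = gamma_op x xi_p`.
#'
#' @param cloud a pose-normalised [point_cloud()].
#' @param ground the normalised [ground_plane()] (`b = 0`).
#' @param keypts optional [locate_keypoints()] result restricting the ridge
#'   range to `[a_P5, a_P4]`.
#' @param slab_width ridge slab thickness (`NULL` = 40 slabs).
#' @return object of class `symmetry_model` with fields `gamma_op`, `xi_p`,
#'   `phi_p`, `mu0`, `mu1`, `tail`, `c0_tail` and `ridge` (the fitted
#'   ridge points).
#' @export
symmetry_plane <- function(cloud, ground, keypts = NULL, slab_width = NULL) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  lo <- min(pts[, 1L]); hi <- max(pts[, 1L])
  if (!is.null(keypts)) {
    lo <- max(lo, keypts$P5[1L])
    hi <- min(hi, keypts$P4[1L])
  }
  sel <- pts[, 1L] >= lo & pts[, 1L] <= hi
  sub <- pts[sel, , drop = FALSE]
  if (nrow(sub) < 12L) stop("too few points in the ridge range")
  if (is.null(slab_width)) slab_width <- (hi - lo) / 40
  ridge <- slab_extremes(sub, (lo + hi) / 2, slab_width,
                         n_slabs = 20L, direction = 1L)
  if (nrow(ridge) < 5L) stop("too few ridge points to fit a symmetry line")
  rc <- tryCatch(
    statistical_outlier_filter(point_cloud(ridge), k = min(5L, nrow(ridge) - 1L),
                               alpha = 2)$points,
    error = function(e) ridge)
  fit <- lm.fit(cbind(1, rc[, 1L]), rc[, 3L])
  gamma_op <- ground$normal
  xi_p <- c(1, 0, 0)
  tail_pt <- unname(pts[which.min(pts[, 1L]), ])
  structure(list(gamma_op = gamma_op, xi_p = xi_p,
                 phi_p = unit(cross3(gamma_op, xi_p)),
                 mu0 = unname(fit$coefficients[1L]),
                 mu1 = unname(fit$coefficients[2L]),
                 tail = tail_pt, c0_tail = tail_pt[3L],
                 ridge = rc),
            class = "symmetry_model")
}

#' @export
print.symmetry_model <- function(x, ...) {
  cat(sprintf("<symmetry_model: c = %.5f %+.5f a; tail c0 = %.5f>\n",
              x$mu0, x$mu1, x$c0_tail))
  invisible(x)
}

# Signed lateral distance of points to the symmetry line c = mu0 + mu1 a.
symmetry_distance <- function(model, pts) {
  (pts[, 3L] - model$mu0 - model$mu1 * pts[, 1L]) / sqrt(1 + model$mu1^2)
}

#' Reflect points across the symmetry plane
#'
#' The vertical coordinate is untouched; `(a, c)` are reflected across the
#' top-view line `c = mu0 + mu1 a`. With `mu1 = 0` this is the paper's
#' homogeneous map `c' = 2 c0 - c`. The map is an involutive isometry.
#'
#' @param points n x 3 matrix (or [point_cloud()]).
#' @param model a [symmetry_plane()] result.
#' @export
reflect_points <- function(points, model) {
  pts <- if (is_point_cloud(points)) points$points else as.matrix(points)
  u <- c(1, model$mu1) / sqrt(1 + model$mu1^2)   # line direction in (a, c)
  w_a <- pts[, 1L]
  w_c <- pts[, 3L] - model$mu0
  proj <- w_a * u[1L] + w_c * u[2L]
  out <- pts
  out[, 1L] <- 2 * proj * u[1L] - w_a
  out[, 3L] <- model$mu0 + 2 * proj * u[2L] - w_c
  out
}

#' Mirror a half-body cloud across the symmetry plane
#'
#' Keeps the points on one side of the fitted symmetry line (`side =
#' "auto"` picks the side holding the majority of points), reflects them to
#' the other side, and returns the union. Reflected points are labelled
#' `"mirrored"`.
#'
#' @param cloud a pose-normalised [point_cloud()].
#' @param model a [symmetry_plane()] result.
#' @param side `"auto"`, `"positive"` or `"negative"` lateral side to keep.
#' @export
mirror_cloud <- function(cloud, model, side = c("auto", "positive",
                                                "negative")) {
  side <- match.arg(side)
  stopifnot(is_point_cloud(cloud))
  s <- symmetry_distance(model, cloud$points)
  sgn <- switch(side,
                auto = if (sum(s > 0) >= sum(s < 0)) 1 else -1,
                positive = 1,
                negative = -1)
  keep <- sgn * s > 0
  if (!any(keep)) stop("no points on the requested side of the symmetry plane")
  half <- subset_cloud(cloud, keep)
  refl <- point_cloud(reflect_points(half$points, model),
                      labels = rep("mirrored", n_points(half)),
                      frame = cloud$frame)
  if (is.null(half$labels)) half$labels <- rep("original", n_points(half))
  bind_clouds(half, refl)
}
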