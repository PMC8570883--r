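# Ground-truthed synthetic quadruped: a lofted superellipse body of
# revolution with an abdomen bulge, a shoulder bulge, a withers crest and
# four cylindrical legs, standing on the plane b = 0. All six body
# parameters (and the chest circumference) are computable from the profile
# functions, so the full pipeline can be scored without captured data.
#
# Profile model (a = longitudinal coordinate, x = a / L):
#   envelope  env(x) = (4 x (1 - x))^0.3          (0 at snout and tail tip)
#   width     w(a)   = env * (r0 + r_ab q(a; a_ab, l_ab) + r_sh q(a; a_sh, l_sh))
#   top       t(a)   = z_c + k (env + 0.632 q(a; a_w, l_w))
#   bottom    d(a)   = z_c - k (env + 0.316 q(a; a_ab, l_belly))
# with q(a; c, l) = exp(-((a - c)/l)^4) (flat-topped bulges, so landmark
# stations are robust to slab discretisation). r_ab, r_sh are solved so the
# lateral semi-axes at the abdomen and shoulder stations equal the spec
# fields exactly; k and z_c are solved the same way for the vertical
# semi-axis and the withers height.

quartic_bump <- function(a, center, len) exp(-((a - center) / len)^4)

envelope <- function(x) (pmax(4 * x * (1 - x), 0))^0.3

#' Synthetic animal specification
#'
#' Defaults describe a market-weight pig: 1.6 m body, 0.85 m withers
#' height, 0.55 m abdominal width, 0.44 m chest depth.
#'
#' @param body_length body length in metres (tail tip at `a = 0`, snout at
#'   `a = body_length`).
#' @param abdomen_radius_b vertical semi-axis at the abdomen station (m).
#' @param abdomen_radius_c lateral semi-axis at the abdomen station (m).
#' @param shoulder_halfwidth lateral semi-axis at the shoulder station (m).
#' @param withers_height ground-to-withers height (m).
#' @param leg_radius leg cylinder radius (m).
#' @param points_per_m2 surface sampling density.
#' @param section_exponent superellipse exponent of body cross-sections.
#' @param seed RNG seed (ground jitter in [generate_scene()]).
#' @export
animal_spec <- function(body_length = 1.6, abdomen_radius_b = 0.22,
                        abdomen_radius_c = 0.275,
                        shoulder_halfwidth = 0.215,
                        withers_height = 0.85, leg_radius = 0.035,
                        points_per_m2 = 6000, section_exponent = 2.5,
                        seed = 1L) {
  sp <- list(body_length = body_length,
             abdomen_radius_b = abdomen_radius_b,
             abdomen_radius_c = abdomen_radius_c,
             shoulder_halfwidth = shoulder_halfwidth,
             withers_height = withers_height,
             leg_radius = leg_radius,
             points_per_m2 = points_per_m2,
             section_exponent = section_exponent,
             seed = as.integer(seed))
  if (any(unlist(sp[1:6]) <= 0)) stop("all dimensions must be positive")
  structure(sp, class = "animal_spec")
}

# Build the closed-form profile functions and landmark stations for a spec.
animal_profiles <- function(spec) {
  L <- spec$body_length
  a_ab <- 0.45 * L; l_ab <- 0.1125 * L
  a_sh <- 0.80 * L; l_sh <- 0.069 * L
  r0 <- 0.44 * spec$abdomen_radius_c
  # solve r_ab, r_sh so the semi-axes at the two stations are exact
  e_ab <- envelope(a_ab / L); e_sh <- envelope(a_sh / L)
  q1 <- quartic_bump(a_ab, a_sh, l_sh)   # shoulder leak at abdomen
  q2 <- quartic_bump(a_sh, a_ab, l_ab)   # abdomen leak at shoulder
  rhs <- c(spec$abdomen_radius_c / e_ab - r0,
           spec$shoulder_halfwidth / e_sh - r0)
  sol <- solve(matrix(c(1, q2, q1, 1), 2L, 2L), rhs)
  r_ab <- sol[1L]; r_sh <- sol[2L]
  if (r_ab <= 0) stop("abdomen must be wider than the base body")
  w_fun <- function(a) {
    envelope(a / L) * (r0 + r_ab * quartic_bump(a, a_ab, l_ab) +
                         r_sh * quartic_bump(a, a_sh, l_sh))
  }
  # landmark stations from the width profile (dense grid)
  ag <- seq(0.005 * L, 0.998 * L, length.out = 4000L)
  wg <- w_fun(ag)
  i1 <- which.max(wg)
  a1 <- ag[i1]
  ahead <- ag > a1
  c_ref <- (min(wg[ahead]) + max(wg[ahead])) / 2
  i2 <- which(ahead & wg < c_ref)[1L]
  a2 <- ag[i2]
  # P3: first drop below the reference after the shoulder bulge has risen
  beyond <- which(ag > a2)
  omega <- sign(wg[beyond] - c_ref)
  seen_pos <- cumsum(omega > 0) > 0
  i3 <- beyond[which(omega < 0 & c(FALSE, head(seen_pos, -1L)))[1L]]
  a3 <- ag[i3]
  seg <- which(ag >= a2 & ag <= a3)
  cd <- chord_distance(ag[seg], wg[seg], c(a2, wg[i2]), c(a3, wg[i3]))
  a4 <- ag[seg[which.max(cd)]]
  # vertical profiles: withers crest centred between P2 and P4
  a_w <- (a2 + a4) / 2; l_w <- 0.1375 * L; l_belly <- 0.15 * L
  t_raw <- function(a) envelope(a / L) + 0.632 * quartic_bump(a, a_w, l_w)
  d_raw <- function(a) -envelope(a / L) - 0.316 * quartic_bump(a, a_ab, l_belly)
  k <- spec$abdomen_radius_b / ((t_raw(a1) - d_raw(a1)) / 2)
  z_c <- spec$withers_height - k * max(t_raw(ag))
  if (z_c <= 0.05) stop("withers height too small for the body depth")
  t_fun <- function(a) z_c + k * t_raw(a)
  d_fun <- function(a) z_c + k * d_raw(a)
  a6 <- ag[which.max(t_fun(ag))]
  list(L = L, w = w_fun, t = t_fun, d = d_fun,
       m = function(a) (t_fun(a) + d_fun(a)) / 2,
       sb = function(a) (t_fun(a) - d_fun(a)) / 2,
       a1 = a1, a2 = a2, a3 = a3, a4 = a4, a6 = a6, a_w = a_w,
       z_c = z_c, leg_a = c(0.24, 0.76) * L,
       leg_c = 0.33 * spec$abdomen_radius_c)
}

# signed |u|^e preserving sign: superellipse coordinate map
se_pow <- function(u, e) sign(u) * abs(u)^e

# polygonal perimeter of the superellipse cross-section at station a
section_perimeter <- function(prof, a, n_exp, n_poly = 2000L) {
  phi <- seq(0, 2 * pi, length.out = n_poly + 1L)
  e <- 2 / n_exp
  cc <- prof$w(a) * se_pow(cos(phi), e)
  bb <- prof$m(a) + prof$sb(a) * se_pow(sin(phi), e)
  sum(sqrt(diff(cc)^2 + diff(bb)^2))
}

#' Generate a ground-truthed synthetic animal
#'
#' Samples the quadruped surface on a deterministic grid (so identical
#' specs give bit-identical clouds) and returns exact key points and body
#' parameters computed from the profile functions, plus the ground plane
#' `b = 0` the legs stand on.
#'
#' @param spec an [animal_spec()].
#' @return list with `cloud` (labelled `body`/`leg`, with outward normals),
#'   `keypoints` (ground truth), `parameters` (ground-truth
#'   [body_parameters()], chest circumference at the shoulder station),
#'   `ground`, `profiles` and `spec`.
#' @export
generate_animal <- function(spec = animal_spec()) {
  stopifnot(inherits(spec, "animal_spec"))
  prof <- animal_profiles(spec)
  L <- prof$L
  n_exp <- spec$section_exponent
  e <- 2 / n_exp
  spacing <- 1 / sqrt(spec$points_per_m2)
  K <- max(20L, as.integer(round(L / spacing)))
  a_grid <- (seq_len(K) - 0.5) / K * L
  pts <- vector("list", K + 4L)
  nrm <- vector("list", K + 4L)
  for (i in seq_len(K)) {
    a <- a_grid[i]
    w <- prof$w(a); sb <- prof$sb(a); m <- prof$m(a)
    per <- section_perimeter(prof, a, n_exp, 72L)
    n_i <- max(8L, 4L * as.integer(round(per / spacing / 4)))
    phi <- 2 * pi * (seq_len(n_i) - 1L) / n_i
    cphi <- cos(phi); sphi <- sin(phi)
    cc <- w * se_pow(cphi, e)
    bb <- m + sb * se_pow(sphi, e)
    # outward normal of the superellipse (transverse plane; the small
    # longitudinal slope component is ignored -- only culling uses these)
    gb <- se_pow(sphi, e * (n_exp - 1)) / sb
    gc <- se_pow(cphi, e * (n_exp - 1)) / w
    nn <- sqrt(gb^2 + gc^2)
    pts[[i]] <- cbind(a, bb, cc)
    nrm[[i]] <- cbind(0, gb / nn, gc / nn)
  }
  # legs: vertical cylinders from the ground to the belly
  leg_id <- 0L
  for (al in prof$leg_a) for (cl in c(-1, 1) * prof$leg_c) {
    leg_id <- leg_id + 1L
    top <- prof$d(al) + 0.03
    nh <- max(4L, as.integer(round(top / spacing)))
    np <- max(8L, as.integer(round(2 * pi * spec$leg_radius / spacing)))
    hh <- (seq_len(nh) - 0.5) / nh * top
    psi <- 2 * pi * (seq_len(np) - 1L) / np
    g <- expand.grid(h = hh, psi = psi)
    pts[[K + leg_id]] <- cbind(al + spec$leg_radius * cos(g$psi), g$h,
                               cl + spec$leg_radius * sin(g$psi))
    nrm[[K + leg_id]] <- cbind(cos(g$psi), 0, sin(g$psi))
  }
  n_body <- sum(vapply(pts[seq_len(K)], nrow, 1L))
  n_leg <- sum(vapply(pts[K + 1:4], nrow, 1L))
  cloud <- point_cloud(do.call(rbind, pts),
                       labels = c(rep("body", n_body), rep("leg", n_leg)),
                       normals = do.call(rbind, nrm))
  if (n_points(cloud) < 500L) {
    warning("fewer than 500 surface points; key points may be unstable")
  }
  a1 <- prof$a1; a4 <- prof$a4
  kp <- structure(list(
    P1 = c(a1, prof$m(a1), prof$w(a1)),
    P2 = c(prof$a2, prof$m(prof$a2), prof$w(prof$a2)),
    P3 = c(prof$a3, prof$m(prof$a3), prof$w(prof$a3)),
    P4 = c(a4, prof$m(a4), prof$w(a4)),
    P5 = c(0, prof$z_c, 0),
    P6 = c(prof$a6, prof$t(prof$a6), 0),
    PU = c(a1, prof$t(a1), 0),
    PD = c(a1, prof$d(a1), 0),
    meta = list(a_P1 = a1, a_P2 = prof$a2, a_P3 = prof$a3, a_P4 = a4)),
    class = "keypoints")
  truth <- body_parameters(
    diagonal_length = sqrt(sum((kp$P4 - kp$P5)^2)),
    horizontal_length = abs(kp$P4[1L] - kp$P5[1L]),
    shoulder_width = 2 * prof$w(a4),
    abdominal_width = 2 * prof$w(a1),
    height = prof$t(prof$a6),
    depth = prof$t(a1) - prof$d(a1),
    # heart girth: behind the forelegs, midway between abdomen and shoulder
    circumference = section_perimeter(prof, (a1 + a4) / 2, n_exp))
  list(cloud = cloud, keypoints = kp, parameters = truth,
       ground = ground_plane(c(0, 1, 0), 0), profiles = prof, spec = spec)
}

#' Generate a full capture scene (animal plus ground)
#'
#' Adds a jittered grid of ground points on `b = 0` around the animal.
#'
#' @param spec an [animal_spec()].
#' @param ground_margin margin around the body footprint in metres.
#' @param ground_density ground points per square metre.
#' @return as [generate_animal()], with ground points (label `"ground"`)
#'   appended to `cloud`.
#' @export
generate_scene <- function(spec = animal_spec(), ground_margin = 0.35,
                           ground_density = 1200) {
  scene <- generate_animal(spec)
  L <- spec$body_length
  ar <- c(-ground_margin, L + ground_margin)
  cr <- c(-1, 1) * (spec$abdomen_radius_c + 2 * ground_margin)
  s <- 1 / sqrt(ground_density)
  g <- expand.grid(a = seq(ar[1L], ar[2L], by = s),
                   c = seq(cr[1L], cr[2L], by = s))
  ng <- nrow(g)
  g <- with_seed(spec$seed, {
    g + matrix(runif(2L * ng, -s / 3, s / 3), ng, 2L)
  })
  groundc <- point_cloud(cbind(g$a, 0, g$c),
                         labels = rep("ground", ng),
                         normals = cbind(0, 1, 0)[rep(1L, ng), ])
  scene$cloud <- bind_clouds(scene$cloud, groundc)
  scene
}

#' Camera pose from position and viewing target
#'
#' Builds a camera-to-world `rigid_transform` whose translation is the
#' camera centre and whose third axis looks at `target`.
#'
#' @param position,target length-3 points in world coordinates.
#' @param up approximate up direction.
#' @export
camera_pose <- function(position, target, up = c(0, 1, 0)) {
  f <- unit(target - position)
  r <- unit(cross3(up, f))
  u <- cross3(f, r)
  rigid_transform(cbind(r, u, f), position)
}

#' Relative pose between two camera frames
#'
#' The `rigid_transform` mapping coordinates in `from`'s frame to
#' coordinates in `to`'s frame.
#' @param from,to camera-to-world `rigid_transform`s.
#' @export
relative_pose <- function(from, to) {
  compose_transforms(invert_transform(to), from)
}

#' Split a cloud into per-camera views
#'
#' Per camera, keeps the points whose outward normal faces the camera
#' centre (back-face culling; no ray-cast self-occlusion) and transforms
#' them into the camera frame with the inverse pose. Ground-truth
#' view-to-view transforms are recoverable via [relative_pose()].
#'
#' @param cloud a [point_cloud()] with normals (required when `cull`).
#' @param poses list of >= 2 camera-to-world `rigid_transform`s.
#' @param cull apply back-face culling.
#' @return list of [point_cloud()]s, one per camera, each with its pose in
#'   attribute `"pose"`.
#' @export
split_views <- function(cloud, poses, cull = TRUE) {
  stopifnot(is_point_cloud(cloud))
  if (length(poses) < 2L) stop("need at least 2 camera poses")
  if (cull && is.null(cloud$normals)) {
    stop("cloud has no normals; generate with generate_animal() or set cull = FALSE")
  }
  lapply(seq_along(poses), function(i) {
    pose <- poses[[i]]
    keep <- if (cull) {
      rowSums(cloud$normals *
                sweep(-cloud$points, 2L, -pose$p)) > 0
    } else rep(TRUE, n_points(cloud))
    if (!any(keep)) warning("camera ", i, " sees no points")
    v <- apply_transform(invert_transform(pose), subset_cloud(cloud, keep),
                         frame = paste0("camera", i))
    attr(v, "pose") <- pose
    v
  })
}

#' Delete points occluded by railing bars
#'
#' Removes the points within bands `|coordinate - position| < bar_width/2`
#' on the given axis, emulating fence railings between camera and animal;
#' the deleted points are returned separately as repair ground truth.
#'
#' @param cloud a [point_cloud()].
#' @param bar_axis axis the bands cut across (default `"b"`: horizontal
#'   rails at fixed heights).
#' @param bar_positions band centres in metres.
#' @param bar_width band width in metres.
#' @return list with `cloud` (kept points) and `removed`.
#' @export
add_railing_occlusion <- function(cloud, bar_axis = "b",
                                  bar_positions = numeric(0),
                                  bar_width = 0.05) {
  stopifnot(is_point_cloud(cloud))
  if (bar_width <= 0) stop("bar_width must be positive")
  v <- cloud$points[, axis_col(bar_axis)]
  hit <- rep(FALSE, length(v))
  for (p in bar_positions) hit <- hit | abs(v - p) < bar_width / 2
  list(cloud = subset_cloud(cloud, !hit),
       removed = subset_cloud(cloud, hit))
}

#' Add sensor noise and outliers
#'
#' Adds isotropic Gaussian jitter (`sigma` per coordinate) and replaces
#' `round(outlier_fraction * n)` randomly chosen points with uniform draws
#' inside a 3x-scaled bounding box (labelled `"outlier"`).
#'
#' @param cloud a [point_cloud()].
#' @param sigma jitter standard deviation in metres.
#' @param outlier_fraction fraction of points replaced by outliers.
#' @param seed RNG seed.
#' @export
add_noise <- function(cloud, sigma, outlier_fraction = 0, seed = NULL) {
  stopifnot(is_point_cloud(cloud), sigma >= 0,
            outlier_fraction >= 0, outlier_fraction < 1)
  n <- n_points(cloud)
  if (n == 0L) return(cloud)
  with_seed(seed, {
    pts <- cloud$points
    if (sigma > 0) pts <- pts + matrix(rnorm(3L * n, sd = sigma), n, 3L)
    labels <- cloud$labels
    n_out <- round(outlier_fraction * n)
    if (n_out > 0L) {
      ctr <- colMeans(pts)
      half <- 1.5 * (apply(pts, 2L, max) - apply(pts, 2L, min))
      idx <- sample.int(n, n_out)
      pts[idx, ] <- matrix(runif(3L * n_out, -1, 1), n_out, 3L) *
        rep(half, each = n_out) + rep(ctr, each = n_out)
      if (is.null(labels)) labels <- rep("original", n)
      labels[idx] <- "outlier"
    }
    point_cloud(pts, labels = labels, frame = cloud$frame,
                normals = cloud$normals)
  })
}
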