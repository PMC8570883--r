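# Multiview registration: stereo-extrinsic composition, coarse alignment by
# 4-point congruent sets (affine-invariant intersection-distance ratios),
# ICP refinement, and stitching.

#' Stereo calibration pair
#'
#' Poses of two cameras relative to a common calibration object:
#' `O1 = G1 O + p1`, `O2 = G2 O + p2` for a world point `O`.
#'
#' @param G1,G2 3x3 rotation matrices.
#' @param p1,p2 length-3 translations in metres.
#' @export
stereo_calibration <- function(G1, p1, G2, p2) {
  # rigid_transform() performs the orthonormality validation
  structure(list(cam1 = rigid_transform(G1, p1),
                 cam2 = rigid_transform(G2, p2)),
            class = "stereo_calibration")
}

#' Compose stereo extrinsics into a camera-2 -> camera-1 transform
#'
#' Returns `(G, p)` with `G = G1 G2^T`, `p = p1 - G p2`, which satisfies
#' `O1 = G O2 + p` for any world point pushed through the calibration.
#'
#' @param calib a [stereo_calibration()].
#' @export
compose_stereo <- function(calib) {
  stopifnot(inherits(calib, "stereo_calibration"))
  G <- calib$cam1$G %*% t(calib$cam2$G)
  rigid_transform(G, calib$cam1$p - drop(G %*% calib$cam2$p))
}

#' Distance ratio of three collinear points
#'
#' `g = |U - V| / |U - W|`, the affine-invariant ratio fixed by three known
#' collinear points.
#' @param U,V,W length-3 points.
#' @export
distance_ratio <- function(U, V, W) {
  d <- sqrt(sum((U - W)^2))
  if (d < 1e-300) stop("U and W coincide")
  sqrt(sum((U - V)^2)) / d
}

# Closest points between lines U + t1 (W - U) and V + t2 (Q - V).
# Returns NULL when the lines are parallel.
line_closest <- function(U, W, V, Q) {
  d1 <- W - U; d2 <- Q - V; r <- V - U
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  den <- a * cc - b * b
  if (den <= 1e-12 * a * cc || a == 0 || cc == 0) return(NULL)
  e <- sum(d1 * r); f <- sum(d2 * r)
  t1 <- (cc * e - b * f) / den
  t2 <- (b * e - a * f) / den
  h1 <- U + t1 * d1; h2 <- V + t2 * d2
  list(t1 = t1, t2 = t2, h1 = h1, h2 = h2,
       gap = sqrt(sum((h1 - h2)^2)))
}

#' Affine-invariant ratios of a coplanar 4-point base
#'
#' Intersects the lines U-W and V-Q (closest-point midpoint in 3D) and
#' returns the two intersection-distance ratios
#' `g1 = |U - H| / |U - W|`, `g2 = |V - H| / |V - Q|`.
#'
#' @param U,V,W,Q length-3 points; segments U-W and V-Q must intersect
#'   within both segments.
#' @param tol maximum allowed gap between the two lines, as a fraction of
#'   the mean segment length.
#' @return an object of class `coplanar_base` with fields `U`, `V`, `W`,
#'   `Q`, `H`, `g1`, `g2`.
#' @export
base_ratios <- function(U, V, W, Q, tol = 1e-6) {
  U <- as.numeric(U); V <- as.numeric(V)
  W <- as.numeric(W); Q <- as.numeric(Q)
  cl <- line_closest(U, W, V, Q)
  if (is.null(cl)) stop("no intersection: lines U-W and V-Q are parallel")
  scale <- (sqrt(sum((W - U)^2)) + sqrt(sum((Q - V)^2))) / 2
  if (cl$gap > tol * scale) {
    stop("no intersection: lines are skew beyond tolerance (gap = ",
         format(cl$gap), ")")
  }
  if (cl$t1 < -1e-9 || cl$t1 > 1 + 1e-9 || cl$t2 < -1e-9 || cl$t2 > 1 + 1e-9) {
    stop("no intersection: lines meet outside the segments")
  }
  H <- (cl$h1 + cl$h2) / 2
  structure(list(U = U, V = V, W = W, Q = Q, H = H,
                 g1 = distance_ratio(U, H, W),
                 g2 = distance_ratio(V, H, Q)),
            class = "coplanar_base")
}

#' Candidate intersection points from a target point pair
#'
#' `h1 = s1 + g1 (s2 - s1)`, `h2 = s1 + g2 (s2 - s1)`.
#' @param s1,s2 length-3 points.
#' @param g1,g2 ratios in `[0, 1]`.
#' @export
candidate_intersections <- function(s1, s2, g1, g2) {
  if (g1 < 0 || g1 > 1 || g2 < 0 || g2 > 1) {
    stop("ratios must lie in [0, 1]")
  }
  d <- s2 - s1
  list(h1 = s1 + g1 * d, h2 = s1 + g2 * d)
}

# Sample a wide, approximately coplanar 4-point base from `pts` whose
# diagonals U-W / V-Q intersect inside both segments. Returns NULL on
# failure.
sample_base <- function(pts, diag_len, span_frac = 0.35) {
  n <- nrow(pts)
  for (attempt in seq_len(40L)) {
    tri <- sample.int(n, 3L)
    A <- pts[tri[1L], ]; B <- pts[tri[2L], ]; C <- pts[tri[3L], ]
    dmin <- min(sqrt(sum((A - B)^2)), sqrt(sum((A - C)^2)),
                sqrt(sum((B - C)^2)))
    if (dmin < span_frac * diag_len) next
    nv <- cross3(B - A, C - A)
    area <- sqrt(sum(nv^2)) / 2
    if (area < 0.02 * diag_len^2) next
    nv <- nv / sqrt(sum(nv^2))
    cand <- sample.int(n, min(n, 200L))
    cand <- setdiff(cand, tri)
    pd <- abs(drop(sweep(pts[cand, , drop = FALSE], 2L, A) %*% nv))
    for (ci in cand[order(pd)][seq_len(min(25L, length(cand)))]) {
      D <- pts[ci, ]
      quad <- rbind(A, B, C, D)
      for (pr in list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L),
                      c(1L, 4L, 2L, 3L))) {
        U <- quad[pr[1L], ]; W <- quad[pr[2L], ]
        V <- quad[pr[3L], ]; Q <- quad[pr[4L], ]
        cl <- line_closest(U, W, V, Q)
        if (is.null(cl)) next
        if (cl$t1 < 0.05 || cl$t1 > 0.95 || cl$t2 < 0.05 || cl$t2 > 0.95) next
        if (cl$gap > 0.02 * diag_len) next
        H <- (cl$h1 + cl$h2) / 2
        return(list(U = U, W = W, V = V, Q = Q,
                    g1 = distance_ratio(U, H, W),
                    g2 = distance_ratio(V, H, Q),
                    d1 = sqrt(sum((W - U)^2)),
                    d2 = sqrt(sum((Q - V)^2))))
      }
    }
  }
  NULL
}

#' Coarse registration by 4-point congruent sets
#'
#' Repeatedly samples a wide coplanar base from `source`, computes its
#' affine-invariant intersection ratios, scans `target` point pairs for
#' pairs whose candidate intersections coincide within `delta`, estimates a
#' rigid transform from each congruent 4-set, and returns the transform
#' that best aligns a source subsample with the target.
#'
#' @param source,target [point_cloud()]s with at least 4 points each.
#' @param delta coincidence/verification tolerance in metres.
#' @param n_bases number of bases to try.
#' @param seed RNG seed.
#' @param target_subsample cap on target points used in the pair scan.
#' @param verify_n source subsample size used for verification.
#' @param min_inlier_frac minimum verified inlier fraction; below it the
#'   alignment is declared failed.
#' @param source_up,target_up optional known shared direction in each
#'   cloud's frame (e.g. the per-view ground-plane normal): candidate
#'   transforms that rotate `source_up` more than `up_max_angle` away from
#'   `target_up` are rejected. This vetoes the flipped pseudo-symmetries a
#'   roughly prolate body admits at coarse tolerance.
#' @param up_max_angle maximum up-vector mismatch in radians.
#' @return the best `rigid_transform` (source -> target), with the verified
#'   inlier fraction in attribute `"score"`.
#' @export
coarse_4pcs <- function(source, target, delta = 0.01, n_bases = 8,
                        seed = NULL, target_subsample = 600,
                        verify_n = 300, min_inlier_frac = 0.25,
                        source_up = NULL, target_up = NULL,
                        up_max_angle = 0.35) {
  stopifnot(is_point_cloud(source), is_point_cloud(target))
  X <- source$points; Y <- target$points
  if (nrow(X) < 4L || nrow(Y) < 4L) stop("both clouds need at least 4 points")
  with_seed(seed, {
    rng <- apply(X, 2L, range)
    diag_len <- sqrt(sum((rng[2L, ] - rng[1L, ])^2))
    if (diag_len <= 0) stop("source cloud is degenerate")
    Ys <- Y[sample.int(nrow(Y), min(nrow(Y), target_subsample)), ,
            drop = FALSE]
    Xv <- X[sample.int(nrow(X), min(nrow(X), verify_n)), , drop = FALSE]
    D <- as.matrix(stats::dist(Ys))
    best <- NULL; best_score <- -Inf; best_rms <- Inf
    tried <- 0L
    for (b in seq_len(n_bases)) {
      base <- sample_base(X, diag_len)
      if (is.null(base)) next
      tried <- tried + 1L
      pairs_for <- function(dlen) {
        hit <- which(abs(D - dlen) < 2 * delta & upper.tri(D),
                     arr.ind = TRUE)
        if (nrow(hit)) rbind(hit, hit[, 2:1, drop = FALSE]) else hit
      }
      pr1 <- pairs_for(base$d1)
      pr2 <- pairs_for(base$d2)
      if (!nrow(pr1) || !nrow(pr2)) next
      h1 <- Ys[pr1[, 1L], , drop = FALSE] +
        base$g1 * (Ys[pr1[, 2L], , drop = FALSE] -
                     Ys[pr1[, 1L], , drop = FALSE])
      h2 <- Ys[pr2[, 1L], , drop = FALSE] +
        base$g2 * (Ys[pr2[, 2L], , drop = FALSE] -
                     Ys[pr2[, 1L], , drop = FALSE])
      nn <- cpp_nn1(h1, h2)
      ok <- which(nn$dist <= delta)
      if (!length(ok)) next
      ok <- ok[order(nn$dist[ok])][seq_len(min(80L, length(ok)))]
      src4 <- rbind(base$U, base$W, base$V, base$Q)
      for (m in ok) {
        tgt4 <- rbind(Ys[pr1[m, 1L], ], Ys[pr1[m, 2L], ],
                      Ys[pr2[nn$idx[m], 1L], ], Ys[pr2[nn$idx[m], 2L], ])
        tf <- tryCatch(fit_rigid(src4, tgt4), error = function(e) NULL)
        if (is.null(tf)) next
        if (!is.null(source_up) && !is.null(target_up)) {
          cosang <- sum(drop(tf$G %*% unit(source_up)) * unit(target_up))
          if (cosang < cos(up_max_angle)) next
        }
        dv <- cpp_nn1(apply_transform(tf, Xv), Y)$dist
        score <- mean(dv <= delta)
        rms <- sqrt(mean(pmin(dv, delta)^2))
        if (score > best_score ||
            (score == best_score && rms < best_rms)) {
          best <- tf; best_score <- score; best_rms <- rms
        }
      }
    }
    if (is.null(best) || best_score < min_inlier_frac) {
      stop(sprintf(paste0("4PCS alignment failure: best inlier fraction ",
                          "%.3f < %.3f (bases tried: %d, delta = %g); ",
                          "check overlap or loosen delta"),
                   max(best_score, 0), min_inlier_frac, tried, delta))
    }
    # refine the 4-point estimate on its verified inliers (standard
    # largest-common-pointset polish; still coarse, not ICP)
    for (r in 1:2) {
      nn <- cpp_nn1(apply_transform(best, Xv), Y)
      keep <- nn$dist <= 2 * delta
      if (sum(keep) < 4L) break
      best2 <- tryCatch(fit_rigid(Xv[keep, , drop = FALSE],
                                  Y[nn$idx[keep], , drop = FALSE]),
                        error = function(e) NULL)
      if (is.null(best2)) break
      best <- best2
    }
    attr(best, "score") <- best_score
    best
  })
}

#' Iterative closest point refinement
#'
#' Alternates nearest-neighbour correspondence with the closed-form
#' least-squares rigid fit (SVD of the cross-covariance,
#' reflection-corrected) until the change in the mean squared
#' correspondence error drops below `eps` or `max_iter` is reached.
#'
#' @param source,target non-empty [point_cloud()]s.
#' @param init initial `rigid_transform` (source -> target).
#' @param max_iter iteration cap.
#' @param eps convergence threshold on the error decrement (metres^2).
#' @param trim correspondences farther than `trim` times the median
#'   nearest-neighbour distance are dropped from the fit (robustness to
#'   partial overlap); `Inf` disables trimming.
#' @return list with `transform`, `error` (final mean squared error),
#'   `errors` (per-iteration error sequence) and `iterations`.
#' @export
icp <- function(source, target, init = rt_identity(), max_iter = 50,
                eps = 1e-12, trim = Inf) {
  stopifnot(is_point_cloud(source), is_point_cloud(target))
  if (n_points(source) == 0L || n_points(target) == 0L) {
    stop("both clouds must be non-empty")
  }
  X <- source$points; Y <- target$points
  tf <- init
  errors <- numeric(0)
  for (it in seq_len(max_iter)) {
    Xt <- apply_transform(tf, X)
    nn <- cpp_nn1(Xt, Y)
    err <- mean(nn$dist^2)
    errors <- c(errors, err)
    if (it > 1L && abs(errors[it - 1L] - err) < eps) break
    keep <- if (is.finite(trim)) {
      nn$dist <= trim * max(median(nn$dist), .Machine$double.eps)
    } else rep(TRUE, nrow(X))
    if (sum(keep) < 3L) break
    tf <- fit_rigid(X[keep, , drop = FALSE],
                    Y[nn$idx[keep], , drop = FALSE])
  }
  final <- mean(cpp_nn1(apply_transform(tf, X), Y)$dist^2)
  list(transform = tf, error = final, errors = errors, iterations = it)
}

#' Stitch registered views into one cloud
#'
#' Applies one transform per view (pass [rt_identity()] for the reference
#' view, or supply one fewer transform than views and the first view is
#' taken as reference) and concatenates. Optionally collapses coincident
#' points within `merge_radius` to their voxel centroid.
#'
#' @param views list of [point_cloud()]s.
#' @param transforms list of `rigid_transform`s into the reference frame.
#' @param merge_radius voxel size in metres for duplicate removal
#'   (`NULL` = keep everything).
#' @export
stitch <- function(views, transforms, merge_radius = NULL) {
  if (length(transforms) == length(views) - 1L) {
    transforms <- c(list(rt_identity()), transforms)
  }
  if (length(transforms) != length(views)) {
    stop("need one transform per view (or one fewer, first view reference)")
  }
  moved <- Map(function(v, tf) apply_transform(tf, v, frame = "stitched"),
               views, transforms)
  out <- do.call(bind_clouds, moved)
  if (is.null(merge_radius)) return(out)
  key <- apply(round(sweep(out$points, 2L, apply(out$points, 2L, min)) /
                       merge_radius), 1L, paste, collapse = "|")
  f <- factor(key, levels = unique(key))
  pts <- rowsum(out$points, f, reorder = FALSE) /
    as.vector(table(f)[levels(f)])
  labels <- if (!is.null(out$labels)) out$labels[!duplicated(key)]
  point_cloud(pts, labels = labels, frame = out$frame)
}
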