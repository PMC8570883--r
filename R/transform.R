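# Rigid transforms: x' = G x + p with G a proper rotation. Scale is fixed at
# 1 and the perspective vector at zero, so the homogeneous 4x4 form is
# [G p; 0 1].

#' Construct a rigid transform
#'
#' @param G 3x3 rotation matrix (orthonormal, determinant +1).
#' @param p length-3 translation vector in metres.
#' @param tol orthonormality tolerance.
#' @return an object of class `rigid_transform` with fields `G`, `p`, and the
#'   fixed `A = 1` scale and `U = 0` perspective components.
#' @export
rigid_transform <- function(G, p = c(0, 0, 0), tol = 1e-6) {
  G <- as.matrix(G)
  p <- as.numeric(p)
  if (!identical(dim(G), c(3L, 3L))) stop("G must be 3x3")
  if (length(p) != 3L) stop("p must have length 3")
  if (max(abs(crossprod(G) - diag(3))) > tol) {
    stop("G is not orthonormal within tolerance")
  }
  if (abs(det(G) - 1) > tol) stop("det(G) must be +1 (no reflections)")
  structure(list(G = G, p = p, A = 1, U = c(0, 0, 0)),
            class = "rigid_transform")
}

#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform: angle %.4f rad, |p| %.4f m>\n",
              rotation_angle(x$G), sqrt(sum(x$p^2))))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param tf a `rigid_transform`.
#' @param x a `pcloud` or an n x 3 matrix.
#' @param frame optional new frame identifier for the transformed cloud.
#' @export
apply_transform <- function(tf, x, frame = NULL) {
  if (is_point_cloud(x)) {
    pts <- x$points %*% t(tf$G)
    pts <- sweep(pts, 2L, -tf$p)
    normals <- if (!is.null(x$normals)) x$normals %*% t(tf$G)
    point_cloud(pts, labels = x$labels, frame = frame %||% x$frame,
                normals = normals)
  } else {
    x <- as.matrix(x)
    sweep(x %*% t(tf$G), 2L, -tf$p)
  }
}

#' Compose rigid transforms
#'
#' `compose_transforms(f, g)` is the transform applying `g` first, then `f`.
#' @export
compose_transforms <- function(f, g) {
  rigid_transform(f$G %*% g$G, drop(f$G %*% g$p) + f$p)
}

#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$G), drop(-t(tf$G) %*% tf$p))
}

#' Rotation angle of a rotation matrix (radians)
#' @export
rotation_angle <- function(G) {
  acos(min(1, max(-1, (sum(diag(G)) - 1) / 2)))
}

#' Rotation about an axis (Rodrigues)
#'
#' @param axis length-3 axis (any norm) or one of `"a"`, `"b"`, `"c"`.
#' @param angle rotation angle in radians.
#' @export
rotation_about_axis <- function(axis, angle) {
  if (is.character(axis)) {
    axis <- c(a = 1, b = 2, c = 3)[[axis]]
    axis <- replace(numeric(3), axis, 1)
  }
  k <- unit(as.numeric(axis))
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Minimal rotation carrying unit-ish vector u onto v.
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  ax <- cross3(u, v)
  s <- sqrt(sum(ax^2))
  cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(cross3(u, ref), pi))
  }
  rotation_about_axis(ax, atan2(s, cth))
}

# Least-squares rigid transform mapping X onto Y (Kabsch / SVD of the
# cross-covariance, reflection-corrected). X, Y are matched n x 3 matrices.
fit_rigid <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  H <- crossprod(sweep(X, 2L, cx), sweep(Y, 2L, cy))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  G <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(G, cy - drop(G %*% cx))
}
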