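# Point-cloud data model. A cloud is a plain list holding an n x 3 double
# matrix of coordinates (columns a, b, c; metres), optional per-point labels,
# optional per-point unit normals, and a frame identifier.
#
# Axis convention (project-wide): a = longitudinal (tail -> head, positive
# toward the head), b = vertical (ground normal), c = lateral (left-right).

AXES <- c(a = 1L, b = 2L, c = 3L)

axis_col <- function(axis) {
  if (is.numeric(axis) && axis %in% 1:3) return(as.integer(axis))
  i <- AXES[[match.arg(as.character(axis), names(AXES))]]
  i
}

#' Construct a point cloud
#'
#' @param points numeric matrix (or coercible) with 3 columns `a`, `b`, `c`,
#'   coordinates in metres.
#' @param labels optional per-point category tags (character or integer),
#'   same length as the number of points.
#' @param frame identifier of the coordinate frame the points live in.
#' @param normals optional n x 3 matrix of outward unit normals (used by the
#'   synthetic view splitter for back-face culling).
#' @return an object of class `pcloud`.
#' @export
point_cloud <- function(points, labels = NULL, frame = "world",
                        normals = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (ncol(points) != 3L) stop("points must have exactly 3 columns (a, b, c)")
  storage.mode(points) <- "double"
  if (nrow(points) && any(!is.finite(points))) {
    stop("all coordinates must be finite")
  }
  colnames(points) <- names(AXES)
  if (!is.null(labels) && length(labels) != nrow(points)) {
    stop("labels must have the same length as points")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    if (!identical(dim(normals), dim(points))) {
      stop("normals must match the dimensions of points")
    }
    storage.mode(normals) <- "double"
  }
  structure(list(points = points, labels = labels, normals = normals,
                 frame = frame),
            class = "pcloud")
}

#' @export
is_point_cloud <- function(x) inherits(x, "pcloud")

#' Number of points in a cloud
#' @param cloud a `pcloud`.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
as.matrix.pcloud <- function(x, ...) x$points

#' @export
print.pcloud <- function(x, ...) {
  cat(sprintf("<pcloud: %d points, frame '%s'%s%s>\n", n_points(x), x$frame,
              if (!is.null(x$labels)) ", labelled" else "",
              if (!is.null(x$normals)) ", with normals" else ""))
  invisible(x)
}

#' Subset a cloud by row index or logical mask
#'
#' Labels and normals are carried along.
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              frame = cloud$frame,
              normals = if (!is.null(cloud$normals))
                cloud$normals[idx, , drop = FALSE])
}

#' Concatenate point clouds
#'
#' The frame is taken from the first cloud; labels are kept whenever any
#' part has them (unlabelled parts get NA tags); normals are kept only when
#' every part has them.
#' @param ... [point_cloud()]s.
#' @export
bind_clouds <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, n_points, 1L) > 0L |
                   seq_along(parts) == 1L]
  pts <- do.call(rbind, lapply(parts, function(p) p$points))
  any_lab <- any(vapply(parts, function(p) !is.null(p$labels), TRUE))
  labels <- if (any_lab) {
    unlist(lapply(parts, function(p) {
      p$labels %||% rep(NA_character_, n_points(p))
    }), use.names = FALSE)
  }
  all_norm <- all(vapply(parts, function(p) !is.null(p$normals), TRUE))
  normals <- if (all_norm) do.call(rbind, lapply(parts, `[[`, "normals"))
  point_cloud(pts, labels = labels, frame = parts[[1L]]$frame,
              normals = normals)
}

#' Construct a ground plane
#'
#' The plane `tau_a a + tau_b b + tau_c c + upsilon = 0`; the normal is
#' renormalised to unit length (and the offset rescaled accordingly).
#'
#' @param normal length-3 normal vector `(tau_a, tau_b, tau_c)`.
#' @param offset scalar offset `upsilon` in metres.
#' @export
ground_plane <- function(normal, offset) {
  normal <- as.numeric(normal)
  if (length(normal) != 3L || !all(is.finite(normal))) {
    stop("normal must be a finite length-3 vector")
  }
  nrm <- sqrt(sum(normal^2))
  if (nrm < 1e-12) stop("normal must be non-zero")
  structure(list(normal = normal / nrm, offset = as.numeric(offset) / nrm),
            class = "ground_plane")
}

#' Signed distance from points to a plane
#'
#' @param plane a `ground_plane`.
#' @param x a `pcloud` or an n x 3 matrix.
#' @param signed return signed distances (default) or absolute values.
#' @export
plane_distance <- function(plane, x, signed = TRUE) {
  pts <- if (is_point_cloud(x)) x$points else as.matrix(x)
  d <- drop(pts %*% plane$normal) + plane$offset
  if (signed) d else abs(d)
}

# Total least-squares plane through a point set (smallest eigenvector of the
# centred covariance). Returns a ground_plane.
fit_plane_lsq <- function(pts) {
  ctr <- colMeans(pts)
  e <- eigen(crossprod(sweep(pts, 2L, ctr)), symmetric = TRUE)
  n <- e$vectors[, 3L]
  ground_plane(n, -sum(n * ctr))
}

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-300) stop("cannot normalise a zero vector")
  v / n
}
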