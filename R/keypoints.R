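# Anatomical key points on silhouette ranges of a pose-normalised cloud.
# All finders reduce to small geometric searches (max perpendicular distance
# to a chord, first sign change of the angle sequence, kNN centroid), each
# testable against exhaustive brute force.

#' Silhouette ranges of a pose-normalised cloud
#'
#' Cuts the cloud into slabs along the longitudinal axis `a` and extracts,
#' per slab, the extreme-width point of the top-view projection (maximum
#' `c`) and the extreme-height points of the side-view projection (maximum
#' and minimum `b`). Ordinates are additionally smoothed by sliding-window
#' cubic polynomial fits to suppress sampling jitter in the slope analysis.
#'
#' @param cloud a pose-normalised [point_cloud()] (ground normal along +b).
#' @param slab_width slab thickness in metres; default spans the cloud with
#'   60 slabs.
#' @param smooth_window odd window size for the local cubic fit (`< 5`
#'   disables smoothing).
#' @param extreme_tol plateau tolerance in metres: the per-slab extreme is
#'   the centroid of all points within this distance of the extreme value.
#' @return list with data frames `top`, `back`, `belly`; each has columns
#'   `a` (slab centre), `v` (raw ordinate), `vs` (smoothed ordinate) and a
#'   `point` matrix of the originating 3D points.
#' @export
silhouette <- function(cloud, slab_width = NULL, smooth_window = 7,
                       extreme_tol = 0.0015) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  if (is.null(slab_width)) {
    slab_width <- (max(pts[, 1L]) - min(pts[, 1L])) / 60
  }
  ss <- slice_cloud(cloud, axis = "a", eps = slab_width)
  range_of <- function(col, direction) {
    rows <- lapply(seq_len(ss$M_S), function(i) {
      idx <- ss$slabs[[i]]
      if (!length(idx)) return(NULL)   # empty slab: skipped
      sub <- pts[idx, , drop = FALSE]
      pt <- plateau_centroid(sub, col, direction, tol = extreme_tol)
      list(a = ss$a_min + (i - 0.5) * ss$eps, v = pt[col], point = pt)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    a <- vapply(rows, `[[`, 0, "a")
    v <- vapply(rows, `[[`, 0, "v")
    pmat <- t(vapply(rows, `[[`, numeric(3), "point"))
    data.frame(a = a, v = v, vs = smooth_range(a, v, smooth_window),
               point = I(pmat))
  }
  list(top = range_of(3L, 1L),
       back = range_of(2L, 1L),
       belly = range_of(2L, -1L))
}

# Sliding-window cubic polynomial smoothing of an ordered range.
smooth_range <- function(a, v, window = 7) {
  n <- length(v)
  if (window < 5 || n < 5) return(v)
  h <- (window - 1) %/% 2
  out <- v
  for (i in seq_len(n)) {
    w <- max(1L, i - h):min(n, i + h)
    if (length(w) < 5L) next
    aw <- a[w] - a[i]
    X <- cbind(1, aw, aw^2, aw^3)
    fit <- tryCatch(lm.fit(X, v[w]), error = function(e) NULL)
    if (!is.null(fit) && fit$rank == 4L) out[i] <- fit$coefficients[1L]
  }
  out
}

# Perpendicular distances of range points to the chord joining two points.
chord_distance <- function(a, v, p_start, p_end) {
  da <- p_end[1L] - p_start[1L]
  dv <- p_end[2L] - p_start[2L]
  len <- sqrt(da^2 + dv^2)
  if (len < 1e-12) stop("degenerate chord: endpoints coincide")
  abs(da * (v - p_start[2L]) - dv * (a - p_start[1L])) / len
}

#' Point of maximum abdominal width (P1)
#'
#' The silhouette point furthest from the chord joining the first and last
#' points of the fitted (smoothed) range.
#'
#' @param top_sil the `top` data frame from [silhouette()] (>= 3 rows).
#' @return list with `point` (3D), `a`, `v`, `index` and `distance`; a
#'   collinear range is flagged via `degenerate = TRUE`.
#' @export
find_P1 <- function(top_sil) {
  n <- nrow(top_sil)
  if (n < 3L) stop("need at least 3 silhouette points")
  d <- chord_distance(top_sil$a, top_sil$vs,
                      c(top_sil$a[1L], top_sil$vs[1L]),
                      c(top_sil$a[n], top_sil$vs[n]))
  i <- which.max(d)
  list(point = as.numeric(top_sil$point[i, ]), a = top_sil$a[i],
       v = top_sil$vs[i], index = i, distance = d[i],
       degenerate = d[i] < 1e-9)
}

#' First positive-to-negative transition of the angle sequence
#'
#' For each candidate beyond the start point, the angle
#' `omega_i = arctan((v_i - v_s) / (a_i - a_s))` to the start point is
#' computed; the transition is the first candidate with `omega < 0` after
#' some earlier candidate had `omega > 0`.
#'
#' @param range2d data frame with columns `a` and an ordinate (`vs` if
#'   present, else `v`), ordered by increasing `a`.
#' @param start length-2 reference point `(a_s, v_s)`.
#' @param gate_min optional ordinate gate: candidates with ordinate below
#'   it are excluded before the scan.
#' @return list with `point` (3D, when the range carries points), `a`,
#'   `v`, `index` (into `range2d`).
#' @export
slope_transition <- function(range2d, start, gate_min = NULL) {
  v <- range2d$vs %||% range2d$v
  keep <- which(range2d$a > start[1L] + 1e-12)
  if (!is.null(gate_min)) keep <- keep[v[keep] >= gate_min]
  if (length(keep) < 2L) {
    stop_not_found("no candidates beyond the start point")
  }
  omega <- atan((v[keep] - start[2L]) / (range2d$a[keep] - start[1L]))
  seen_pos <- cumsum(omega > 0) > 0
  hit <- which(omega < 0 & c(FALSE, head(seen_pos, -1L)))
  if (!length(hit)) {
    stop_not_found("angle sequence never turns from positive to negative")
  }
  i <- keep[hit[1L]]
  out <- list(a = range2d$a[i], v = v[i], index = i)
  if (!is.null(range2d$point)) out$point <- as.numeric(range2d$point[i, ])
  out
}

stop_not_found <- function(msg) {
  stop(structure(class = c("pcm_not_found", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Shoulder point (P4)
#'
#' The range point between P2 and P3 farthest from the chord joining them.
#'
#' @param range2d silhouette data frame (as in [slope_transition()]).
#' @param P2,P3 results of the two transition searches (need `a`, `v`).
#' @export
find_P4 <- function(range2d, P2, P3) {
  v <- range2d$vs %||% range2d$v
  lo <- min(P2$a, P3$a); hi <- max(P2$a, P3$a)
  sel <- which(range2d$a >= lo & range2d$a <= hi)
  if (!length(sel)) stop("empty silhouette segment between P2 and P3")
  d <- chord_distance(range2d$a[sel], v[sel], c(P2$a, P2$v), c(P3$a, P3$v))
  i <- sel[which.max(d)]
  out <- list(a = range2d$a[i], v = v[i], index = i, distance = max(d),
              degenerate = max(d) < 1e-9)
  if (!is.null(range2d$point)) out$point <- as.numeric(range2d$point[i, ])
  out
}

#' Point of ischial tuberosity (P5)
#'
#' Centroid of the `k` points nearest (Euclidean) to the extreme point in
#' the negative direction of axis `a` (the tail point).
#'
#' @param cloud a [point_cloud()].
#' @param k neighbour count; clamped to the cloud size with a warning.
#' @export
find_P5 <- function(cloud, k = 12) {
  stopifnot(is_point_cloud(cloud))
  pts <- cloud$points
  n <- nrow(pts)
  if (k > n) {
    warning("k exceeds the cloud size; clamping to ", n)
    k <- n
  }
  tail_pt <- pts[which.min(pts[, 1L]), ]
  d <- sqrt(rowSums(sweep(pts, 2L, tail_pt)^2))
  unname(colMeans(pts[order(d)[seq_len(k)], , drop = FALSE]))
}

# Centroid of all the points within `tol` of a column's extreme ("all the
# tallest points" rather than the single argmax: robust to the +2-3 sigma
# order-statistic bias of a per-slab maximum under sensor noise).
plateau_centroid <- function(sub, col, direction, tol) {
  v <- sub[, col]
  sel <- if (direction > 0) v >= max(v) - tol else v <= min(v) + tol
  unname(colMeans(sub[sel, , drop = FALSE]))
}

# Per-slab extreme-plateau centroids in 2*n_slabs slabs centred on
# a_center; widened (with a warning) when slabs come up empty.
slab_extremes <- function(pts, a_center, slab_width, n_slabs, direction,
                          tol = 0.004) {
  for (scale in c(1, 1.5, 2.25)) {
    w <- slab_width * scale
    edges <- a_center + (-n_slabs:n_slabs) * w
    rows <- list()
    for (s in seq_len(2L * n_slabs)) {
      inslab <- which(pts[, 1L] >= edges[s] & pts[, 1L] < edges[s + 1L])
      if (!length(inslab)) next
      rows[[length(rows) + 1L]] <-
        plateau_centroid(pts[inslab, , drop = FALSE], 2L, direction, tol)
    }
    if (length(rows) >= n_slabs) {          # at least half the slabs hit
      if (scale > 1) warning("empty key-point slabs; widened search window")
      return(do.call(rbind, rows))
    }
  }
  stop("no points found around a = ", format(a_center))
}

#' Point of withers (P6)
#'
#' Centroid of the tallest points of the `n_slabs` slabs extended to each
#' side of the a-midpoint of P2 and P4.
#'
#' @param cloud a pose-normalised [point_cloud()].
#' @param a_mid longitudinal midpoint of P2 and P4 in metres.
#' @param slab_width slab thickness in metres.
#' @param n_slabs slabs per side.
#' @export
find_P6 <- function(cloud, a_mid, slab_width, n_slabs = 2) {
  colMeans(slab_extremes(cloud$points, a_mid, slab_width, n_slabs, 1L))
}

#' Upper and lower depth points (PU, PD)
#'
#' Centroids of the per-slab tallest and lowest points of the `n_slabs`
#' slabs extended to each side of P1's a-coordinate.
#'
#' @param cloud a pose-normalised [point_cloud()].
#' @param a_P1 longitudinal coordinate of P1 in metres.
#' @param slab_width slab thickness in metres.
#' @param n_slabs slabs per side.
#' @return list with `PU` and `PD` (3D points).
#' @export
find_PU_PD <- function(cloud, a_P1, slab_width, n_slabs = 2) {
  list(PU = colMeans(slab_extremes(cloud$points, a_P1, slab_width,
                                   n_slabs, 1L)),
       PD = colMeans(slab_extremes(cloud$points, a_P1, slab_width,
                                   n_slabs, -1L)))
}

#' Key-point detection configuration
#'
#' @param slab_width silhouette slab thickness in metres (`NULL` = 60 slabs
#'   across the cloud).
#' @param smooth_window sliding cubic smoothing window (points).
#' @param k_p5 neighbour count for the tail centroid P5.
#' @param n_slabs slabs per side for P6/PU/PD.
#' @export
keypoint_config <- function(slab_width = NULL, smooth_window = 7,
                            k_p5 = 12, n_slabs = 2) {
  list(slab_width = slab_width, smooth_window = smooth_window,
       k_p5 = k_p5, n_slabs = n_slabs)
}

#' Locate all anatomical key points
#'
#' Runs the full key-point procedure on a pose-normalised cloud: P1 on the
#' top-view width range; P2 and P3 as the angle-sequence transitions
#' bracketing the shoulder (reference ordinate `(c_min + c_max)/2` of the
#' search range, with the height gate and an ungated fallback for P3); P4 as
#' the max-chord-distance point between them; P5 as the tail kNN centroid;
#' P6, PU, PD as slab-extreme centroids.
#'
#' @param cloud a pose-normalised [point_cloud()].
#' @param config a [keypoint_config()].
#' @return an object of class `keypoints`: named 3D points `P1`..`P6`,
#'   `PU`, `PD` plus a `meta` list of silhouette details.
#' @export
locate_keypoints <- function(cloud, config = keypoint_config()) {
  sil <- silhouette(cloud, slab_width = config$slab_width,
                    smooth_window = config$smooth_window)
  top <- sil$top
  slabw <- if (nrow(top) > 1L) median(diff(top$a)) else 0.03
  p1 <- find_P1(top)
  ahead <- top[top$a > p1$a, , drop = FALSE]
  if (nrow(ahead) < 3L) stop("too few silhouette slabs ahead of P1")
  c_ref <- (min(ahead$vs) + max(ahead$vs)) / 2
  p2 <- slope_transition(top, start = c(p1$a, c_ref))
  p3 <- tryCatch(
    slope_transition(top, start = c(p2$a, p2$v), gate_min = c_ref),
    pcm_not_found = function(e) {
      warning("P3 height gate exhausted candidates; retrying ungated")
      slope_transition(top, start = c(p2$a, p2$v))
    })
  p4 <- find_P4(top, p2, p3)
  p5 <- find_P5(cloud, k = config$k_p5)
  p6 <- find_P6(cloud, a_mid = (p2$a + p4$a) / 2, slab_width = slabw,
                n_slabs = config$n_slabs)
  ud <- find_PU_PD(cloud, a_P1 = p1$a, slab_width = slabw,
                   n_slabs = config$n_slabs)
  structure(list(P1 = p1$point, P2 = p2$point, P3 = p3$point,
                 P4 = p4$point, P5 = p5, P6 = p6,
                 PU = ud$PU, PD = ud$PD,
                 meta = list(a_P1 = p1$a, a_P2 = p2$a, a_P3 = p3$a,
                             a_P4 = p4$a, slab_width = slabw,
                             c_ref = c_ref)),
            class = "keypoints")
}

#' @export
print.keypoints <- function(x, ...) {
  cat("<keypoints>\n")
  for (nm in c("P1", "P2", "P3", "P4", "P5", "P6", "PU", "PD")) {
    cat(sprintf("  %-2s: % .4f % .4f % .4f\n", nm, x[[nm]][1L],
                x[[nm]][2L], x[[nm]][3L]))
  }
  invisible(x)
}
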